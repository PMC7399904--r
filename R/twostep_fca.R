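#' Facility supply-demand ratios (2SFCA step one)
#'
#' For each facility j, searches for communities within the radius `d0` and
#' divides its bed count S_j by the elderly population inside the catchment:
#' R_j = S_j / sum of D_k over k with d_kj <= d0 (boundary inclusive). A
#' facility whose catchment holds no positive demand gets ratio 0, with a
#' warning naming it: unreachable supply is treated as unusable rather than
#' infinite.
#'
#' @param reg A [region()].
#' @param d0 Search radius in meters (> 0). The study defaults are 500 and
#'   600 m, bracketing the acceptable walking range of the elderly.
#' @return Numeric vector of per-facility ratios, beds per person.
#' @export
supply_demand_ratios <- function(reg, d0) {
  stopifnot(inherits(reg, "region"))
  W <- kernel_indicator(d0)(reg$distances)
  fca_core(reg, W, paste0("d0=", d0, " m"))$ratios
}

#' Community accessibility scores (2SFCA step two)
#'
#' For each community i, sums the supply-demand ratios of all facilities
#' within the radius: A_i = sum of R_j over j with d_ij <= d0. Units are
#' beds per person; a community with no facility in range scores 0.
#'
#' @inheritParams supply_demand_ratios
#' @param ratios Per-facility ratios from [supply_demand_ratios()] computed
#'   for the same region and radius.
#' @return Numeric vector of per-community scores, beds per person.
#' @export
accessibility_scores <- function(reg, ratios, d0) {
  stopifnot(inherits(reg, "region"))
  if (length(ratios) != nrow(reg$facilities)) {
    stop("ratios length ", length(ratios), " does not match ",
         nrow(reg$facilities), " facilities")
  }
  W <- kernel_indicator(d0)(reg$distances)
  as.numeric(W %*% ratios)
}

#' Run one accessibility model on a region
#'
#' Single entry point for the three model runs compared in the analysis:
#' `"2sfca"` (hard catchment of radius `d0`), `"gravity2s"` (two searches
#' with the supply-demand ratio attenuated by d^(-beta)), and `"potential"`
#' (either that two-step variant, the default, or the plain potential sum
#' of bed counts over decayed distance with no catchment at all).
#'
#' @param reg A [region()].
#' @param model `"2sfca"`, `"potential"` or `"gravity2s"`.
#' @param d0 Search radius in meters (2SFCA only).
#' @param beta Friction coefficient (potential/gravity models); default 1.
#' @param min_distance Distance floor in meters for the power kernel.
#' @param variant For `model = "potential"`: `"two_step"` (default) keeps
#'   the supply-demand ratio structure with two searches; `"plain"` is the
#'   direct potential sum A_i = sum_j M_j / d_ij^beta with facility mass
#'   M_j = beds.
#' @return An `accessibility_result`: list with `model`, `params`, `ids`,
#'   `population`, `ratios` (NULL for plain potential) and `scores`.
#' @export
run_accessibility <- function(reg, model = c("2sfca", "potential", "gravity2s"),
                              d0 = 600, beta = 1, min_distance = 1,
                              variant = c("two_step", "plain")) {
  stopifnot(inherits(reg, "region"))
  model <- match.arg(model)
  variant <- match.arg(variant)
  if (model == "potential" && variant == "two_step") model <- "gravity2s"

  if (model == "2sfca") {
    ratios <- supply_demand_ratios(reg, d0)
    scores <- accessibility_scores(reg, ratios, d0)
    params <- list(d0 = d0)
  } else if (model == "gravity2s") {
    fit <- gravity_two_step(reg, beta = beta, min_distance = min_distance)
    ratios <- fit$ratios
    scores <- fit$scores
    params <- list(beta = beta, min_distance = min_distance)
  } else {
    ratios <- NULL
    scores <- potential_plain(reg, beta = beta, min_distance = min_distance)
    params <- list(beta = beta, min_distance = min_distance)
  }
  if (any(scores < 0) || (!is.null(ratios) && any(ratios < 0))) {
    stop("internal error: negative accessibility") # invariant guard
  }
  structure(list(model = model, params = params,
                 ids = reg$demand$id, population = reg$demand$population,
                 ratios = ratios, scores = scores),
            class = "accessibility_result")
}

#' @export
print.accessibility_result <- function(x, ...) {
  cat("<accessibility_result> model=", x$model, " (",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat("  ", length(x$scores), " units; mean score ",
      signif(mean(x$scores), 4), " beds/person; ",
      sum(x$scores == 0), " zero\n", sep = "")
  invisible(x)
}

#' Tidy per-unit scores from one or more model runs
#'
#' @param ... `accessibility_result` objects (or one list of them).
#' @return Data frame with columns `id`, `population`, `score`, `model`
#'   and the run parameters flattened to `d0`/`beta` columns (NA where not
#'   applicable), stacked across runs.
#' @export
scores_table <- function(...) {
  runs <- list(...)
  if (length(runs) == 1L && !inherits(runs[[1L]], "accessibility_result")) {
    runs <- runs[[1L]]
  }
  do.call(rbind, lapply(runs, function(r) {
    stopifnot(inherits(r, "accessibility_result"))
    data.frame(id = r$ids, population = r$population, score = r$scores,
               model = r$model,
               d0 = if (is.null(r$params$d0)) NA_real_ else r$params$d0,
               beta = if (is.null(r$params$beta)) NA_real_ else r$params$beta,
               stringsAsFactors = FALSE)
  }))
}
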