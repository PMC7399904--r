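#' Combine percentile bands across model runs
#'
#' A community's combined band is the most favorable (lowest-numbered) band
#' it achieved in any run: entering the top decile of even one model is
#' enough to drop it from facility-planning consideration.
#'
#' @param ... Band assignment data frames from [percentile_bands()] (or one
#'   list of them), at least one, all covering identical unit ids.
#' @return Data frame with columns `id` and `combined_band`.
#' @export
combine_runs <- function(...) {
  runs <- list(...)
  if (length(runs) == 1L && is.data.frame(runs[[1L]]) == FALSE) runs <- runs[[1L]]
  stopifnot(length(runs) >= 1L)
  ids <- sort(runs[[1L]]$id)
  bands <- vapply(runs, function(r) {
    if (!setequal(r$id, ids) || length(r$id) != length(ids)) {
      stop("model runs cover different unit ids")
    }
    r$band[match(ids, r$id)]
  }, integer(length(ids)))
  bands <- matrix(bands, nrow = length(ids))
  data.frame(id = ids, combined_band = apply(bands, 1L, min),
             stringsAsFactors = FALSE)
}

#' Priority classes for adding facilities or beds
#'
#' Turns combined bands, zero-in-all-runs flags and an analyst-supplied
#' exclusion list into planning priorities. The rules, in order: an
#' excluded community (e.g. one populated by a campus or park rather than
#' elderly residents) is `not_considered`; a community with zero
#' accessibility in every run is `highest` priority; a community whose
#' combined band is 1 (top decile somewhere) is `not_considered`; bands 2,
#' 3 and 4 map to `very_low`, `low` and `high` — worse accessibility means
#' higher priority. The band-to-class mapping is overridable.
#'
#' @param combined Data frame from [combine_runs()].
#' @param zero_in_all Logical vector aligned with `combined$id` (or a
#'   character vector of ids that scored 0 in every run).
#' @param exclude Character vector of community ids excluded by qualitative
#'   judgment; never inferred from the scores.
#' @param band_classes Named character vector mapping bands 2..k to classes.
#' @return Data frame with columns `id`, `combined_band`, `zero_in_all`,
#'   `excluded`, `priority_class`.
#' @export
priority_classes <- function(combined, zero_in_all, exclude = character(),
                             band_classes = c(`2` = "very_low", `3` = "low",
                                              `4` = "high")) {
  stopifnot(is.data.frame(combined),
            all(c("id", "combined_band") %in% names(combined)))
  if (is.character(zero_in_all)) zero_in_all <- combined$id %in% zero_in_all
  stopifnot(length(zero_in_all) == nrow(combined))
  excluded <- combined$id %in% exclude

  cls <- unname(band_classes[as.character(combined$combined_band)])
  cls[combined$combined_band == 1L] <- "not_considered"
  cls[zero_in_all] <- "highest"
  cls[excluded] <- "not_considered"
  if (anyNA(cls)) {
    stop("no class mapped for band(s): ",
         paste(unique(combined$combined_band[is.na(cls)]), collapse = ", "))
  }
  data.frame(id = combined$id, combined_band = combined$combined_band,
             zero_in_all = zero_in_all, excluded = excluded,
             priority_class = cls, stringsAsFactors = FALSE)
}

#' Full prioritization over a set of model runs
#'
#' Convenience wrapper: bands each run's scores, combines bands, flags
#' communities that scored zero in every run, and assigns priority classes.
#'
#' @param results List of `accessibility_result` objects (>= 2 runs).
#' @param breaks Cumulative band fractions, see [percentile_bands()].
#' @param exclude Ids excluded from consideration (see [priority_classes()]).
#' @return Data frame with per-run bands (`band_<model>`), `combined_band`,
#'   `zero_in_all`, `excluded` and `priority_class`.
#' @export
prioritize_runs <- function(results, breaks = c(0.10, 0.27, 0.45),
                            exclude = character()) {
  stopifnot(is.list(results), length(results) >= 2L)
  run_label <- vapply(results, function(r) {
    p <- r$params
    paste0(r$model, if (!is.null(p$d0)) paste0("_", p$d0))
  }, character(1L))
  if (anyDuplicated(run_label)) {
    run_label <- make.unique(run_label, sep = "_run")
  }
  bands <- lapply(results, function(r) {
    percentile_bands(r$scores, breaks = breaks, ids = r$ids, model = r$model)
  })
  combined <- combine_runs(bands)

  zero_ids <- Reduce(intersect, lapply(results, function(r) r$ids[r$scores == 0]))
  out <- priority_classes(combined, zero_in_all = zero_ids, exclude = exclude)
  for (k in seq_along(bands)) {
    out[[paste0("band_", run_label[k])]] <-
      bands[[k]]$band[match(out$id, bands[[k]]$id)]
  }
  out
}
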