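#' Equal-interval level classification
#'
#' Bins scores into k equal-width intervals spanning from the minimum to the
#' maximum value, the scheme used for the study's choropleth maps (six
#' levels for the 2SFCA runs, five for the potential run). Level 1 is the
#' lowest interval; the maximum score lands in level k. If all scores are
#' equal the range is degenerate and every unit gets level 1.
#'
#' @param scores Numeric vector of accessibility scores, finite.
#' @param k Number of levels, integer >= 1.
#' @param ids Optional unit labels (defaults to score names or indices).
#' @return Data frame with columns `id`, `score`, `level`.
#' @export
equal_interval_levels <- function(scores, k, ids = NULL) {
  if (length(scores) == 0L) stop("no scores to classify")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a positive integer")
  }
  ids <- resolve_ids(scores, ids)
  lo <- min(scores); width <- (max(scores) - lo) / k
  level <- if (width == 0) rep(1L, length(scores)) else {
    pmin(as.integer(floor((scores - lo) / width)) + 1L, as.integer(k))
  }
  data.frame(id = ids, score = as.numeric(scores), level = level,
             stringsAsFactors = FALSE)
}

#' Percentile band assignment for one model run
#'
#' Ranks communities by descending accessibility and cuts the ranking at
#' cumulative fractions of the unit count (defaults: top 10%, 10-27%,
#' 27-45%, remaining 55%), assigning bands 1 (best) through 4 (worst). Rank
#' cutoffs are ceilings of fraction x n. Ties are broken by descending score
#' then ascending id so the assignment is deterministic and independent of
#' input order. Units with score exactly 0 always fall in the bottom band:
#' a zero score must never earn a favorable band, whatever the rank
#' arithmetic says about a run where most scores vanish.
#'
#' @param scores Numeric vector of accessibility scores.
#' @param breaks Strictly increasing cumulative fractions in (0, 1);
#'   default `c(0.10, 0.27, 0.45)`.
#' @param ids Optional unit labels.
#' @param model Optional model label carried into the output.
#' @return Data frame with columns `id`, `score`, `band` (1..length(breaks)+1)
#'   and `model`.
#' @export
percentile_bands <- function(scores, breaks = c(0.10, 0.27, 0.45),
                             ids = NULL, model = NA_character_) {
  if (length(scores) == 0L) stop("no scores to band")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (length(breaks) < 1L || any(breaks <= 0) || any(breaks >= 1) ||
      any(diff(breaks) <= 0)) {
    stop("breaks must be strictly increasing fractions in (0, 1)")
  }
  ids <- resolve_ids(scores, ids)
  n <- length(scores)
  cut_ranks <- ceiling(breaks * n)
  ord <- order(-scores, ids) # deterministic tie-break
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  band <- rep.int(length(breaks) + 1L, n)
  for (b in rev(seq_along(cut_ranks))) band[rank_of <= cut_ranks[b]] <- b
  band[scores == 0] <- length(breaks) + 1L
  data.frame(id = ids, score = as.numeric(scores), band = band,
             model = model, stringsAsFactors = FALSE)
}

resolve_ids <- function(scores, ids) {
  if (is.null(ids)) ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  ids <- as.character(ids)
  if (length(ids) != length(scores)) stop("ids and scores lengths differ")
  check_ids(ids, "unit")
  ids
}
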