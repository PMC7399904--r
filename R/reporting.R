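#' Summary statistics for one accessibility run
#'
#' Mirrors the headline statistics a planner reads off a run: the mean score
#' over all communities (zeros included), how many communities have zero
#' accessibility, how many meet the policy demand threshold (default 0.035
#' beds per person, i.e. 35 beds per 1000 elderly from China's 13th
#' Five-Year Plan), the best community, the worst community with a non-zero
#' score, and that worst score as a percentage of the best. Percentages are
#' reported both raw and rounded to the nearest integer (half away from
#' zero), the form used in report text.
#'
#' @param scores Numeric vector of per-community scores, finite, >= 0.
#' @param populations Optional per-community elderly populations; when
#'   given, a population-weighted mean is also emitted (clearly labeled —
#'   the headline mean is always unweighted).
#' @param ids Optional community labels.
#' @param threshold Demand-meeting threshold in beds per person.
#' @param model Optional run label.
#' @return A `run_summary` list: `model`, `n`, `mean_score`,
#'   `weighted_mean_score` (NA without populations), `n_zero`, `pct_zero`,
#'   `pct_zero_rounded`, `n_meeting`, `pct_meeting`, `pct_meeting_rounded`,
#'   `best_unit`, `best_score`, `worst_nonzero_unit`, `worst_nonzero_score`,
#'   `worst_to_best_pct`, `worst_to_best_pct_rounded`, `threshold`. The
#'   worst-to-best fields are NA when no positive score exists.
#' @export
summarize_run <- function(scores, populations = NULL, ids = NULL,
                          threshold = 0.035, model = NA_character_) {
  if (length(scores) == 0L) stop("no scores to summarize")
  if (!all(is.finite(scores)) || any(scores < 0)) {
    stop("scores must be finite and non-negative")
  }
  ids <- resolve_ids(scores, ids)
  n <- length(scores)
  n_zero <- sum(scores == 0)
  n_meeting <- sum(scores >= threshold)
  best <- which.max(scores)

  pos <- scores > 0
  if (any(pos)) {
    worst_i <- which(pos)[which.min(scores[pos])]
    worst_unit <- ids[worst_i]
    worst_score <- scores[worst_i]
    w2b <- if (scores[best] > 0) 100 * worst_score / scores[best] else NA_real_
  } else {
    worst_unit <- NA_character_; worst_score <- NA_real_; w2b <- NA_real_
  }

  wmean <- if (is.null(populations)) NA_real_ else {
    stopifnot(length(populations) == n)
    if (sum(populations) > 0) {
      sum(scores * populations) / sum(populations)
    } else NA_real_
  }

  structure(list(
    model = model, n = n, threshold = threshold,
    mean_score = mean(scores), weighted_mean_score = wmean,
    n_zero = n_zero, pct_zero = 100 * n_zero / n,
    pct_zero_rounded = round_half_up(100 * n_zero / n),
    n_meeting = n_meeting, pct_meeting = 100 * n_meeting / n,
    pct_meeting_rounded = round_half_up(100 * n_meeting / n),
    best_unit = ids[best], best_score = scores[best],
    worst_nonzero_unit = worst_unit, worst_nonzero_score = worst_score,
    worst_to_best_pct = w2b,
    worst_to_best_pct_rounded = round_half_up(w2b)
  ), class = "run_summary")
}

# nearest integer, halves away from zero (base round() goes to even)
round_half_up <- function(x) {
  ifelse(is.na(x), NA_real_, sign(x) * floor(abs(x) + 0.5))
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>", if (!is.na(x$model)) paste0(" model=", x$model), "\n",
      sep = "")
  cat(sprintf("  mean accessibility: %.4g beds/person over %d communities\n",
              x$mean_score, x$n))
  cat(sprintf("  zero accessibility: %d communities (%d%%)\n",
              x$n_zero, as.integer(x$pct_zero_rounded)))
  cat(sprintf("  meeting demand (>= %.3f): %d communities (%d%%)\n",
              x$threshold, x$n_meeting, as.integer(x$pct_meeting_rounded)))
  cat(sprintf("  best: %s (%.5f)\n", x$best_unit, x$best_score))
  if (!is.na(x$worst_nonzero_unit)) {
    cat(sprintf("  worst non-zero: %s (%.5f), %d%% of the best\n",
                x$worst_nonzero_unit, x$worst_nonzero_score,
                as.integer(x$worst_to_best_pct_rounded)))
  }
  invisible(x)
}
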