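# Deliberately naive reference implementations: explicit loops, scalar
# weight functions, no shared code with the vectorized package paths.

oracle_fca <- function(reg, w) {
  n <- nrow(reg$demand); m <- nrow(reg$facilities)
  ratios <- numeric(m)
  for (j in seq_len(m)) {
    denom <- 0
    for (k in seq_len(n)) {
      denom <- denom + reg$demand$population[k] * w(reg$distances[k, j])
    }
    ratios[j] <- if (denom > 0) reg$facilities$beds[j] / denom else 0
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      scores[i] <- scores[i] + ratios[j] * w(reg$distances[i, j])
    }
  }
  list(ratios = ratios, scores = scores)
}

oracle_indicator <- function(d0) function(d) if (d <= d0) 1 else 0
oracle_power <- function(beta, min_distance = 1) {
  function(d) max(d, min_distance)^(-beta)
}

oracle_potential <- function(reg, beta, min_distance = 1) {
  n <- nrow(reg$demand); m <- nrow(reg$facilities)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      scores[i] <- scores[i] +
        reg$facilities$beds[j] / max(reg$distances[i, j], min_distance)^beta
    }
  }
  scores
}

# a small randomized region; seed determines everything
random_region <- function(seed, n_demand = 12, n_facilities = 8,
                          extent = 2500, ...) {
  generate_region(synth_config(seed = seed, n_demand = n_demand,
                               n_facilities = n_facilities,
                               extent = extent, ...))
}

# demand-weighted score total must equal beds of facilities whose catchment
# holds positive weighted demand
served_supply <- function(reg, W) {
  denom <- as.numeric(crossprod(W, reg$demand$population))
  sum(reg$facilities$beds[denom > 0])
}
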