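#' Distance-weight kernels
#'
#' All three accessibility models share one structure: facility ratios are
#' supply divided by kernel-weighted in-range demand, and scores sum the
#' kernel-weighted ratios reachable from each community. The 2SFCA method is
#' the indicator kernel (weight 1 inside the search radius, 0 outside); the
#' gravity models use a power-law kernel d^(-beta) with a distance floor.
#'
#' @param d0 Search radius in meters (indicator kernel), strictly positive.
#' @return A function mapping a distance matrix (m) to a weight matrix.
#' @name kernels
NULL

#' @rdname kernels
#' @export
kernel_indicator <- function(d0) {
  force(within_radius(matrix(1), d0)) # validates d0
  function(d) (d <= d0) * 1
}

#' @rdname kernels
#' @param beta Dimensionless friction coefficient, >= 0. Larger values make
#'   attraction fall off faster with distance; 0 removes the decay entirely.
#' @param min_distance Floor in meters applied to distances before
#'   exponentiation, guarding against coincident points where d = 0 would
#'   make the power weight undefined.
#' @export
kernel_power <- function(beta = 1, min_distance = 1) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0) {
    stop("beta must be a single non-negative number")
  }
  if (!is.numeric(min_distance) || length(min_distance) != 1L ||
      !is.finite(min_distance) || min_distance <= 0) {
    stop("min_distance must be a single positive number (meters)")
  }
  function(d) pmax(d, min_distance)^(-beta)
}

# Shared floating-catchment core: ratios R_j = S_j / sum_k D_k w(d_kj),
# scores A_i = sum_j R_j w(d_ij). W is the n_demand x n_fac weight matrix.
fca_core <- function(reg, W, warn_label) {
  D <- reg$demand$population
  S <- reg$facilities$beds
  denom <- as.numeric(crossprod(W, D)) # weighted demand per facility
  ratios <- numeric(length(S))
  ok <- denom > 0
  ratios[ok] <- S[ok] / denom[ok]
  if (any(!ok)) {
    warning("facility with no weighted demand in ", warn_label,
            " catchment gets ratio 0: ",
            paste(reg$facilities$id[!ok], collapse = ", "))
  }
  scores <- as.numeric(W %*% ratios)
  list(ratios = ratios, scores = scores)
}
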