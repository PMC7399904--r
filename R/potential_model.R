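#' Plain potential (gravity) accessibility
#'
#' The classical potential of spatial interaction: every facility attracts
#' every community with energy M_j / d_ij^beta, facility mass M_j taken as
#' its bed count, and a community's accessibility is the sum over all
#' facilities. There is no search radius; distance decay alone limits
#' influence. Distances are floored at `min_distance` before exponentiation
#' so coincident points stay defined.
#'
#' @param reg A [region()].
#' @param beta Friction coefficient, >= 0; the study default is 1 (a value
#'   of 2 made results too dispersed to read at this spatial scale).
#' @param min_distance Distance floor in meters, default 1.
#' @return Numeric vector of per-community scores. Note the units are beds
#'   per meter^beta, not beds per person: the plain potential has no demand
#'   term, which is why the two-step variant is the reporting default.
#' @export
potential_plain <- function(reg, beta = 1, min_distance = 1) {
  stopifnot(inherits(reg, "region"))
  W <- kernel_power(beta, min_distance)(reg$distances)
  as.numeric(W %*% reg$facilities$beds)
}

#' Two-step gravity accessibility (attenuated supply-demand ratios)
#'
#' The gravity analogue of the 2SFCA method: two searches, centered first on
#' facilities and then on communities, but with the hard catchment replaced
#' by the power kernel w(d) = max(d, min_distance)^(-beta). Step one forms
#' attenuated ratios R_j = S_j / sum_k D_k w(d_kj); step two sums
#' A_i = sum_j R_j w(d_ij). With beta = 0 this reduces exactly to 2SFCA with
#' an infinite radius, and replacing w by the indicator of d <= d0 recovers
#' 2SFCA itself.
#'
#' @inheritParams potential_plain
#' @return List with `ratios` (per facility, beds per weighted person) and
#'   `scores` (per community, beds per person).
#' @export
gravity_two_step <- function(reg, beta = 1, min_distance = 1) {
  stopifnot(inherits(reg, "region"))
  W <- kernel_power(beta, min_distance)(reg$distances)
  fca_core(reg, W, paste0("gravity (beta=", beta, ")"))
}
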