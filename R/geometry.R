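#' Area-weighted centroid of a planar polygon
#'
#' Computes the geometric center of a community polygon by the shoelace
#' (Gauss) formula. The centroid stands in for the (unknown) center of the
#' elderly population when deriving a community's demand point.
#'
#' @param polygon Numeric matrix with two columns (x, y) in meters, listing
#'   the ring vertices in order. The ring may be open or explicitly closed.
#' @param id Optional unit label used in error messages.
#' @return Numeric vector `c(x, y)`.
#' @examples
#' community_centroid(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' @export
community_centroid <- function(polygon, id = NULL) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L || !is.numeric(polygon)) {
    stop("polygon must be a numeric matrix with >= 3 rows and 2 columns")
  }
  if (!all(is.finite(polygon))) {
    stop("polygon has non-finite coordinates", unit_tag(id))
  }
  # drop an explicit closing vertex so each edge is counted once
  n <- nrow(polygon)
  if (all(polygon[1L, ] == polygon[n, ])) {
    polygon <- polygon[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop("polygon degenerates to fewer than 3 distinct vertices", unit_tag(id))
  x <- polygon[, 1L]; y <- polygon[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  area2 <- sum(cross) # twice the signed area
  if (abs(area2) < .Machine$double.eps * max(1, max(abs(polygon)))^2) {
    stop("polygon has zero area", unit_tag(id))
  }
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (3 * area2)
}

unit_tag <- function(id) if (is.null(id)) "" else paste0(" (unit '", id, "')")

#' Euclidean distance matrix between demand points and facilities
#'
#' Straight-line (not road-network) distances on a projected plane, as used
#' for catchment searches at sub-district scale.
#'
#' @param demand_points Numeric matrix, n x 2, projected coordinates (m).
#' @param facility_points Numeric matrix, m x 2, same coordinate system.
#' @return n x m matrix of distances in meters.
#' @export
distance_matrix <- function(demand_points, facility_points) {
  dp <- as.matrix(demand_points); fp <- as.matrix(facility_points)
  if (ncol(dp) != 2L || ncol(fp) != 2L) stop("point matrices must have 2 columns (x, y)")
  if (!all(is.finite(dp)) || !all(is.finite(fp))) {
    stop("non-finite coordinates in point matrices")
  }
  dx <- outer(dp[, 1L], fp[, 1L], "-")
  dy <- outer(dp[, 2L], fp[, 2L], "-")
  sqrt(dx * dx + dy * dy)
}

#' Catchment incidence at threshold radius
#'
#' Marks which demand-facility pairs fall inside the search radius; the
#' boundary is inclusive (distance equal to `d0` is inside the catchment).
#'
#' @param distances Numeric matrix of distances in meters.
#' @param d0 Threshold radius in meters, strictly positive.
#' @return Logical matrix, same shape as `distances`.
#' @export
within_radius <- function(distances, d0) {
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 <= 0) {
    stop("d0 must be a single positive number (meters)")
  }
  distances <= d0
}
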