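#' Assemble a study region from demand and supply layers
#'
#' A region pairs the community (demand) layer with the facility (supply)
#' layer and caches the straight-line distance matrix between community
#' demand points and facilities. Demand points are polygon centroids where a
#' polygon is supplied, the given point otherwise.
#'
#' @param demand Data frame with columns `id`, `population` and either
#'   `x`/`y` point coordinates or a list-column `geometry` of polygon vertex
#'   matrices (two columns, meters).
#' @param facilities Data frame with columns `id`, `x`, `y`, `beds`.
#' @param crs Optional name of the projected coordinate system, recorded for
#'   provenance only; no geodetic math is performed.
#' @return An object of class `region`: list with elements `demand`
#'   (id, x, y, population), `facilities` (id, x, y, beds), `distances`
#'   (n_demand x n_facilities matrix, meters) and `crs`.
#' @export
region <- function(demand, facilities, crs = NA_character_) {
  demand <- as.data.frame(demand)
  facilities <- as.data.frame(facilities)

  need_d <- c("id", "population")
  if (!all(need_d %in% names(demand))) {
    stop("demand layer is missing column(s): ",
         paste(setdiff(need_d, names(demand)), collapse = ", "))
  }
  if (!is.null(demand$geometry)) {
    pts <- t(vapply(seq_len(nrow(demand)), function(i) {
      community_centroid(demand$geometry[[i]], id = demand$id[i])
    }, numeric(2L)))
    demand$x <- pts[, 1L]
    demand$y <- pts[, 2L]
  }
  if (!all(c("x", "y") %in% names(demand))) {
    stop("demand layer needs x/y coordinates or a geometry column")
  }
  need_f <- c("id", "x", "y", "beds")
  if (!all(need_f %in% names(facilities))) {
    stop("supply layer is missing column(s): ",
         paste(setdiff(need_f, names(facilities)), collapse = ", "))
  }

  demand$id <- as.character(demand$id)
  facilities$id <- as.character(facilities$id)
  check_ids(demand$id, "demand unit")
  check_ids(facilities$id, "facility")
  check_count(demand$population, "population", demand$id)
  check_count(facilities$beds, "beds", facilities$id)

  dist <- distance_matrix(cbind(demand$x, demand$y),
                          cbind(facilities$x, facilities$y))
  dimnames(dist) <- list(demand$id, facilities$id)

  structure(
    list(demand = demand[c("id", "x", "y", "population",
                           intersect("geometry", names(demand)))],
         facilities = facilities[need_f],
         distances = dist,
         crs = crs),
    class = "region")
}

check_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) stop(what, " ids must be non-empty")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate ", what, " id(s): ", paste(dup, collapse = ", "))
  }
  invisible(ids)
}

check_count <- function(v, what, ids) {
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stop(what, " must be finite and numeric")
  }
  if (any(v < 0)) {
    stop("negative ", what, " for id(s): ",
         paste(ids[v < 0], collapse = ", "))
  }
  if (any(v != round(v))) {
    stop(what, " must be whole counts; fractional value for id(s): ",
         paste(ids[v != round(v)], collapse = ", "))
  }
  invisible(v)
}

#' @export
print.region <- function(x, ...) {
  cat("<region> ", nrow(x$demand), " demand units, ",
      nrow(x$facilities), " facilities\n", sep = "")
  cat("  population total: ", sum(x$demand$population),
      "; beds total: ", sum(x$facilities$beds), "\n", sep = "")
  if (!is.na(x$crs)) cat("  crs: ", x$crs, "\n", sep = "")
  invisible(x)
}

#' Validate the internal consistency of a region
#'
#' Checks the cached distance matrix against the coordinates (to 1e-6 m),
#' the matrix shape, and attribute non-negativity.
#'
#' @param x A `region` object.
#' @return Invisibly `x`; errors describe the first violated invariant.
#' @export
validate_region <- function(x) {
  stopifnot(inherits(x, "region"))
  n <- nrow(x$demand); m <- nrow(x$facilities)
  if (!identical(dim(x$distances), c(n, m))) {
    stop("distance matrix shape ", paste(dim(x$distances), collapse = "x"),
         " does not match layers (", n, "x", m, ")")
  }
  if (any(x$distances < 0)) stop("negative distances in cached matrix")
  fresh <- distance_matrix(cbind(x$demand$x, x$demand$y),
                           cbind(x$facilities$x, x$facilities$y))
  if (max(abs(fresh - x$distances)) > 1e-6) {
    stop("cached distance matrix disagrees with coordinates by > 1e-6 m")
  }
  invisible(x)
}
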