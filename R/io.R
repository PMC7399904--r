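#' Read demand and supply layers into a region
#'
#' Accepts GeoJSON (`.geojson`/`.json`, FeatureCollection of Point or
#' Polygon features with `id` and `population`/`beds` properties) or CSV
#' (`id,x,y,population` / `id,x,y,beds`). Coordinates must be planar meters
#' in a projected system; equivalent CSV and GeoJSON encodings produce
#' identical regions.
#'
#' @param demand_path,supply_path Paths to the two layers.
#' @param crs Optional projected-CRS name recorded for provenance.
#' @return A [region()].
#' @export
read_layers <- function(demand_path, supply_path, crs = NA_character_) {
  demand <- read_layer(demand_path, value_col = "population")
  supply <- read_layer(supply_path, value_col = "beds")
  region(demand, supply, crs = crs)
}

read_layer <- function(path, value_col) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    read_geojson_layer(path, value_col)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y", value_col)
    if (!all(need %in% names(df))) {
      stop(path, " is missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    df[need]
  }
}

read_geojson_layer <- function(path, value_col) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop(path, " is not a GeoJSON FeatureCollection")
  }
  rows <- lapply(gj$features, function(f) {
    props <- f$properties
    if (is.null(props$id) || is.null(props[[value_col]])) {
      stop(path, ": every feature needs 'id' and '", value_col,
           "' properties")
    }
    geom <- f$geometry
    if (identical(geom$type, "Point")) {
      xy <- as.numeric(unlist(geom$coordinates))
      list(id = as.character(props$id), x = xy[1L], y = xy[2L],
           value = as.numeric(props[[value_col]]), poly = NULL)
    } else if (identical(geom$type, "Polygon")) {
      ring <- do.call(rbind, lapply(geom$coordinates[[1L]], as.numeric))
      list(id = as.character(props$id), x = NA_real_, y = NA_real_,
           value = as.numeric(props[[value_col]]), poly = ring)
    } else {
      stop(path, ": unsupported geometry type '", geom$type, "'")
    }
  })
  df <- data.frame(id = vapply(rows, `[[`, character(1L), "id"),
                   x = vapply(rows, `[[`, numeric(1L), "x"),
                   y = vapply(rows, `[[`, numeric(1L), "y"),
                   stringsAsFactors = FALSE)
  df[[value_col]] <- vapply(rows, `[[`, numeric(1L), "value")
  polys <- lapply(rows, `[[`, "poly")
  if (all(!vapply(polys, is.null, logical(1L)))) {
    df$geometry <- I(polys)
    df$x <- NULL; df$y <- NULL
  } else if (any(!vapply(polys, is.null, logical(1L)))) {
    stop(path, ": mixed Point and Polygon geometries are not supported")
  }
  df
}

#' Write a region's layers to disk
#'
#' Format follows the file extension: `.geojson`/`.json` writes a GeoJSON
#' FeatureCollection (Polygon features for demand units that carry
#' geometry, Point features otherwise), anything else a CSV in the
#' `id,x,y,population|beds` dialect.
#'
#' @param reg A [region()].
#' @param demand_path,supply_path Output paths.
#' @return Invisibly the two paths.
#' @export
write_layers <- function(reg, demand_path, supply_path) {
  stopifnot(inherits(reg, "region"))
  write_layer(reg$demand, demand_path, "population")
  fac <- reg$facilities
  fac$geometry <- NULL
  write_layer(fac, supply_path, "beds")
  invisible(c(demand_path, supply_path))
}

write_layer <- function(df, path, value_col) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- lapply(seq_len(nrow(df)), function(i) {
      geom <- if (!is.null(df$geometry)) {
        ring <- df$geometry[[i]]
        ring <- rbind(ring, ring[1L, ]) # close the ring
        list(type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(ring)),
                                       function(r) as.numeric(ring[r, ]))))
      } else {
        list(type = "Point", coordinates = c(df$x[i], df$y[i]))
      }
      props <- list(id = df$id[i])
      props[[value_col]] <- df[[value_col]][i]
      list(type = "Feature", geometry = geom, properties = props)
    })
    writeLines(jsonlite::toJSON(list(type = "FeatureCollection",
                                     features = feats),
                                auto_unbox = TRUE, digits = NA), path)
  } else {
    out <- df
    if (!is.null(out$geometry)) {
      if (is.null(out$x)) {
        pts <- t(vapply(out$geometry, community_centroid, numeric(2L)))
        out$x <- pts[, 1L]; out$y <- pts[, 2L]
      }
      out$geometry <- NULL
    }
    utils::write.csv(out[c("id", "x", "y", value_col)], path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Write model results to disk
#'
#' `format = "csv"` writes the tidy `id,population,score,model,d0,beta`
#' table; `"json"` writes a [summarize_run()] summary (raw and rounded
#' fields); `"geojson"` writes one Point feature per community carrying
#' `score` (and `level` when `levels` is given) properties for mapping.
#' Values survive a round-trip to 1e-12.
#'
#' @param result An `accessibility_result` from [run_accessibility()].
#' @param path Output path.
#' @param format `"csv"`, `"json"` or `"geojson"`; defaults from the
#'   extension.
#' @param reg The source [region()], required for `"geojson"` coordinates.
#' @param levels Optional [equal_interval_levels()] table for `"geojson"`.
#' @param ... Passed to [summarize_run()] for `"json"`.
#' @return Invisibly `path`.
#' @export
write_results <- function(result, path, format = NULL, reg = NULL,
                          levels = NULL, ...) {
  stopifnot(inherits(result, "accessibility_result"))
  if (is.null(format)) {
    format <- if (grepl("\\.geojson$", path, ignore.case = TRUE)) "geojson"
              else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  format <- match.arg(format, c("csv", "json", "geojson"))
  if (format == "csv") {
    utils::write.csv(scores_table(result), path, row.names = FALSE)
  } else if (format == "json") {
    smry <- summarize_run(result$scores, populations = result$population,
                          ids = result$ids, model = result$model, ...)
    writeLines(jsonlite::toJSON(unclass(smry), auto_unbox = TRUE,
                                digits = NA, na = "null"), path)
  } else {
    if (is.null(reg)) stop("geojson output needs the source region (reg =)")
    df <- data.frame(id = result$ids, x = reg$demand$x, y = reg$demand$y,
                     score = result$scores, stringsAsFactors = FALSE)
    if (!is.null(levels)) df$level <- levels$level[match(df$id, levels$id)]
    feats <- lapply(seq_len(nrow(df)), function(i) {
      props <- as.list(df[i, setdiff(names(df), c("x", "y")), drop = FALSE])
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])),
           properties = props)
    })
    writeLines(jsonlite::toJSON(list(type = "FeatureCollection",
                                     features = feats),
                                auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' Read a tidy scores CSV back into a data frame
#'
#' @param path CSV written by [write_results()] with `format = "csv"`.
#' @return Data frame with `id, population, score, model, d0, beta`.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "score") %in% names(df))) {
    stop(path, " does not look like a scores table (needs id, score)")
  }
  df
}
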