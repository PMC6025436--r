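#' Point density surface
#'
#' Per grid cell, the number of points within `radius` of the cell center
#' divided by the buffer area pi r^2. The buffer is a disk centered on the
#' cell center; the area normalization cancels after min-max normalization,
#' but keeps raw units interpretable (count per area).
#'
#' @param points two-column matrix / data frame of point coordinates; may be
#'   empty.
#' @param spec grid geometry, a `raster_grid` (e.g. [grid_spec()]).
#' @param radius buffer radius (> 0), default 24 (km).
#' @param dedup drop exact-coordinate duplicate points first (default TRUE).
#' @return a `raster_grid` of densities.
#' @export
point_density <- function(points, spec, radius = 24, dedup = TRUE) {
  stopifnot(radius > 0)
  cc <- cell_centers(spec)
  counts <- matrix(0, spec$nrows, spec$ncols)
  if (!is.null(points) && NROW(points) > 0) {
    P <- as.matrix(as.data.frame(points))[, 1:2, drop = FALSE]
    if (dedup) P <- P[!duplicated(P), , drop = FALSE]
    r2 <- radius^2
    for (k in seq_len(nrow(P))) {
      dx2 <- (cc$x - P[k, 1])^2   # length ncols
      dy2 <- (cc$y - P[k, 2])^2   # length nrows
      counts <- counts + (outer(dy2, dx2, "+") <= r2)
    }
  }
  raster_grid(counts / (pi * radius^2), spec$origin, spec$cell_size,
              spec$crs_label)
}

#' Line density surface
#'
#' Per grid cell, the total polyline length inside the disk of `radius`
#' around the cell center, divided by pi r^2. The segment-disk intersection
#' is solved analytically: the squared distance from the center to the
#' segment is quadratic in the segment parameter, so the chord is the
#' parameter interval between the two roots clipped to [0, 1].
#'
#' @param lines list of polylines, each a two-column matrix of ordered
#'   vertices.
#' @param spec grid geometry (`raster_grid`).
#' @param radius buffer radius (> 0), default 24 (km).
#' @return a `raster_grid`; skipped zero-length segments counted in
#'   attribute `"n_degenerate"`.
#' @export
line_density <- function(lines, spec, radius = 24) {
  stopifnot(radius > 0)
  cc <- cell_centers(spec)
  CX <- rep(cc$x, each = spec$nrows)
  CY <- rep(cc$y, times = spec$ncols)
  total <- numeric(spec$nrows * spec$ncols)
  r2 <- radius^2
  n_degen <- 0L
  for (ln in lines) {
    V <- as.matrix(ln)
    if (nrow(V) < 2L) next
    for (s in seq_len(nrow(V) - 1L)) {
      p <- V[s, ]; q <- V[s + 1L, ]
      dx <- q[1] - p[1]; dy <- q[2] - p[2]
      a <- dx * dx + dy * dy
      if (a == 0) { n_degen <- n_degen + 1L; next }
      # |p + t d - c|^2 = r^2  ->  a t^2 + b t + c0 = 0, per cell center
      ex <- p[1] - CX; ey <- p[2] - CY
      b <- 2 * (dx * ex + dy * ey)
      c0 <- ex * ex + ey * ey - r2
      disc <- b * b - 4 * a * c0
      hit <- disc > 0
      if (!any(hit)) next
      sq <- sqrt(disc[hit])
      t1 <- pmax((-b[hit] - sq) / (2 * a), 0)
      t2 <- pmin((-b[hit] + sq) / (2 * a), 1)
      len <- pmax(t2 - t1, 0) * sqrt(a)
      total[hit] <- total[hit] + len
    }
  }
  out <- raster_grid(matrix(total / (pi * r2), spec$nrows, spec$ncols),
                     spec$origin, spec$cell_size, spec$crs_label)
  attr(out, "n_degenerate") <- n_degen
  out
}

#' Min-max normalization of a raster
#'
#' Maps valid cells linearly onto [0, 1]: `(x - min)/(max - min)`. Nodata
#' is preserved; a constant grid errors (zero denominator).
#'
#' @param grid a `raster_grid` with at least two distinct valid values.
#' @return normalized `raster_grid`.
#' @export
minmax_normalize <- function(grid) {
  v <- grid$values
  ok <- is.finite(v)
  lo <- min(v[ok]); hi <- max(v[ok])
  if (hi == lo) stop("constant grid: min-max normalization undefined")
  raster_grid((v - lo) / (hi - lo), grid$origin, grid$cell_size,
              grid$crs_label)
}

#' Composite pollution-source density
#'
#' Cellwise mean of the normalized road and factory density layers; nodata
#' wherever either input is nodata.
#'
#' @param road_norm,fact_norm aligned `raster_grid`s in [0, 1].
#' @return a `raster_grid` in [0, 1].
#' @export
composite_source_density <- function(road_norm, fact_norm) {
  if (!.same_grid(road_norm, fact_norm))
    stop("normalized density grids are not aligned")
  raster_grid((road_norm$values + fact_norm$values) / 2,
              road_norm$origin, road_norm$cell_size, road_norm$crs_label)
}

#' Read point / line geometries from GeoJSON
#'
#' Supports `Point` (and `MultiPoint`) features for
#' `read_geojson_points()`, `LineString` and `MultiLineString` for
#' `read_geojson_lines()`; FeatureCollection, bare features and bare
#' geometries are all accepted. Coordinates must already be planar.
#'
#' @param path GeoJSON file.
#' @return points: two-column matrix; lines: list of two-column vertex
#'   matrices.
#' @export
read_geojson_points <- function(path) {
  geoms <- .geojson_geometries(path)
  out <- list()
  for (g in geoms) {
    if (identical(g$type, "Point"))
      out[[length(out) + 1L]] <- matrix(unlist(g$coordinates), 1L, 2L)
    else if (identical(g$type, "MultiPoint"))
      out[[length(out) + 1L]] <- do.call(rbind, lapply(g$coordinates,
        function(c2) matrix(unlist(c2), 1L, 2L)))
  }
  if (!length(out)) return(matrix(numeric(0), 0L, 2L))
  unname(do.call(rbind, out))
}

#' @rdname read_geojson_points
#' @export
read_geojson_lines <- function(path) {
  geoms <- .geojson_geometries(path)
  out <- list()
  coords_to_mat <- function(cs)
    do.call(rbind, lapply(cs, function(pt) as.numeric(unlist(pt))[1:2]))
  for (g in geoms) {
    if (identical(g$type, "LineString"))
      out[[length(out) + 1L]] <- coords_to_mat(g$coordinates)
    else if (identical(g$type, "MultiLineString"))
      for (part in g$coordinates)
        out[[length(out) + 1L]] <- coords_to_mat(part)
  }
  out
}

.geojson_geometries <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(j$type, "FeatureCollection"))
    lapply(j$features, `[[`, "geometry")
  else if (identical(j$type, "Feature"))
    list(j$geometry)
  else
    list(j)
}

#' Write geometries as GeoJSON
#'
#' @param points two-column matrix of point coordinates.
#' @param lines list of two-column vertex matrices.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(points, path) {
  P <- as.matrix(points)
  feats <- lapply(seq_len(nrow(P)), function(i)
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Point", coordinates = as.numeric(P[i, 1:2]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_points
#' @export
write_geojson_lines <- function(lines, path) {
  feats <- lapply(lines, function(V) {
    V <- as.matrix(V)
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(V)),
                                              function(i) as.numeric(V[i, 1:2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
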