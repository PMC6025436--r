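#' Monitoring-station set
#'
#' Container for the observational unit of the pipeline: a network of
#' monitoring stations with planar coordinates, a measured exposure value
#' (e.g. PM2.5 concentration in ug/m3) and a matrix of covariates extracted
#' from gridded products (AOD, surface temperature, pressure, relative
#' humidity, boundary-layer height, NDVI, elevation, source densities, ...).
#'
#' Coordinates must be planar (same length unit on both axes, typically km):
#' all distance computations downstream are Euclidean. Longitude/latitude
#' input should be projected first, e.g. with [project_equidistant()].
#'
#' @param station_id vector of unique station labels (coerced to character).
#' @param x,y numeric planar coordinates.
#' @param value numeric exposure measurements.
#' @param covariates data frame or numeric matrix of covariate columns with
#'   unique names; one row per station. May be `NULL` for a bare network.
#' @return An object of class `station_set` with fields `station_id`, `x`,
#'   `y`, `value` and `covariates` (numeric matrix, possibly 0 columns).
#' @export
station_set <- function(station_id, x, y, value, covariates = NULL) {
  station_id <- as.character(station_id)
  x <- as.numeric(x); y <- as.numeric(y); value <- as.numeric(value)
  n <- length(station_id)
  if (n < 3L) stop("a station_set needs at least 3 stations, got ", n)
  if (length(x) != n || length(y) != n || length(value) != n)
    stop("station_id, x, y and value must have equal length")
  if (anyDuplicated(station_id))
    stop("duplicate station_id values: ",
         paste(unique(station_id[duplicated(station_id)]), collapse = ", "))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("station coordinates must be finite")
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    i <- which(dup)[1L]
    j <- which(x == x[i] & y == y[i])[1L]
    stop(sprintf("stations %s and %s share coordinates (%g, %g)",
                 station_id[j], station_id[i], x[i], y[i]))
  }
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n)
      stop("covariates must have one row per station")
    if (is.null(colnames(covariates)) || anyDuplicated(colnames(covariates)))
      stop("covariate columns must have unique names")
  }
  structure(list(station_id = station_id, x = x, y = y, value = value,
                 covariates = covariates),
            class = "station_set")
}

#' @export
print.station_set <- function(x, ...) {
  cat(sprintf("station_set: %d stations, %d covariates (%s)\n",
              length(x$station_id), ncol(x$covariates),
              paste(colnames(x$covariates), collapse = ", ")))
  cat(sprintf("  x range [%g, %g], y range [%g, %g]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  cat(sprintf("  value: mean %.2f, sd %.2f\n", mean(x$value), stats::sd(x$value)))
  invisible(x)
}

#' Number of stations
#' @param stations a `station_set`.
#' @return integer count.
#' @export
n_stations <- function(stations) length(stations$station_id)

#' Read a station table from CSV
#'
#' Expects a header row `station_id,x,y,value,<covariate...>`, UTF-8, '.'
#' decimal separator. Any columns after `value` are treated as covariates.
#'
#' @param path file path.
#' @return a [station_set()].
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("station_id", "x", "y", "value")
  if (!all(need %in% names(df)))
    stop("station CSV must contain columns: ", paste(need, collapse = ", "))
  cov <- df[, setdiff(names(df), need), drop = FALSE]
  station_set(df$station_id, df$x, df$y, df$value,
              if (ncol(cov)) cov else NULL)
}

#' Write a station table to CSV
#' @param stations a `station_set`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_stations <- function(stations, path) {
  df <- data.frame(station_id = stations$station_id, x = stations$x,
                   y = stations$y, value = stations$value,
                   check.names = FALSE)
  if (ncol(stations$covariates))
    df <- cbind(df, as.data.frame(stations$covariates))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Project longitude/latitude to planar kilometres
#'
#' Equidistant cylindrical projection about a reference point: adequate for
#' regional study areas where the pipeline's Euclidean-distance assumption
#' must be met before building spatial weights. The projection used should
#' be recorded in the run configuration for provenance.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param lon0,lat0 reference point; defaults to the centroid of the input.
#' @return list with numeric vectors `x`, `y` in km and the reference point.
#' @export
project_equidistant <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  R <- 6371.0088  # mean Earth radius, km
  rad <- pi / 180
  list(x = R * cos(lat0 * rad) * (lon - lon0) * rad,
       y = R * (lat - lat0) * rad,
       lon0 = lon0, lat0 = lat0)
}
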