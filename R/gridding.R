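#' Raster grid container
#'
#' Minimal single-band raster: a numeric matrix in row-major map order with
#' the origin at the upper-left corner. Cell centers sit at
#' `x = x0 + (j - 0.5) cell`, `y = y0 - (i - 0.5) cell` for row i, column j.
#' `NA` marks nodata; the sentinel only appears in file I/O.
#'
#' @param values numeric matrix (nrows x ncols), `NA` for nodata.
#' @param origin numeric length 2, upper-left corner `(x0, y0)`.
#' @param cell_size positive scalar (same units as station coordinates).
#' @param crs_label free-text label recorded for provenance.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin, cell_size, crs_label = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(length(origin) == 2L, is.finite(origin), cell_size > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size),
                 nrows = nrow(values), ncols = ncol(values),
                 crs_label = crs_label),
            class = "raster_grid")
}

#' @rdname raster_grid
#' @param nrows,ncols grid dimensions for an empty grid.
#' @export
grid_spec <- function(origin, cell_size, nrows, ncols, crs_label = "") {
  raster_grid(matrix(NA_real_, nrows, ncols), origin, cell_size, crs_label)
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("raster_grid: %d x %d, cell %g, origin (%g, %g), %d valid cells\n",
              x$nrows, x$ncols, x$cell_size, x$origin[1], x$origin[2],
              length(v)))
  if (length(v)) cat(sprintf("  range [%.4g, %.4g]\n", min(v), max(v)))
  invisible(x)
}

#' Cell-center coordinates of a raster grid
#' @param grid a `raster_grid`.
#' @return list with `x` (length ncols) and `y` (length nrows, decreasing).
#' @export
cell_centers <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$ncols) - 0.5) * grid$cell_size,
       y = grid$origin[2] - (seq_len(grid$nrows) - 0.5) * grid$cell_size)
}

.same_grid <- function(a, b, tol = 1e-9) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' ESRI ASCII grid I/O
#'
#' Plain-text raster exchange format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header, rows top to bottom).
#'
#' @param grid a `raster_grid`.
#' @param path file path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path` invisibly; `read_ascii_grid()` returns a `raster_grid`.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncols),
               sprintf("nrows %d", grid$nrows),
               sprintf("xllcorner %.10g", grid$origin[1]),
               sprintf("yllcorner %.10g",
                       grid$origin[2] - grid$nrows * grid$cell_size),
               sprintf("cellsize %.10g", grid$cell_size),
               sprintf("NODATA_value %.10g", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  get <- function(k) as.numeric(kv[match(tolower(k), tolower(kv[, 1])), 2])
  ncols <- get("ncols"); nrows <- get("nrows")
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == nrows, ncol(v) == ncols)
  nd <- get("NODATA_value")
  if (!is.na(nd)) v[v == nd] <- NA_real_
  cell <- get("cellsize")
  raster_grid(v, c(get("xllcorner"), get("yllcorner") + nrows * cell), cell)
}

#' Spherical semivariogram
#'
#' `gamma(h) = nugget + (sill - nugget)(1.5 h/range - 0.5 (h/range)^3)` for
#' `0 < h <= range`, `sill` beyond the range, and exactly 0 at h = 0.
#'
#' @param h distances (>= 0).
#' @param nugget,sill,range model parameters, `sill > nugget >= 0`,
#'   `range > 0`.
#' @return semivariance values.
#' @export
spherical_semivariance <- function(h, nugget, sill, range) {
  s <- pmin(h / range, 1)
  g <- nugget + (sill - nugget) * (1.5 * s - 0.5 * s^3)
  g[h == 0] <- 0
  g
}

#' Ordinary kriging with a spherical variogram
#'
#' Best linear unbiased interpolation: for each target the weights solve the
#' semivariance system augmented with the unbiasedness constraint (weights
#' sum to one). With zero nugget the predictor interpolates the data
#' exactly.
#'
#' @param points data frame with columns `x`, `y`, `value` (>= 3 rows, no
#'   duplicate locations).
#' @param variogram list with `nugget`, `sill`, `range`
#'   (e.g. [fit_spherical_variogram()]).
#' @param targets a `raster_grid` (all cell centers predicted) or a
#'   two-column coordinate matrix.
#' @return a `raster_grid` of predictions, or a numeric vector for matrix
#'   targets. Kriging weights for the last solve are attached as attribute
#'   `"weights"` (targets x points).
#' @export
ordinary_kriging <- function(points, variogram, targets) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "value") %in% names(points)))
  n <- nrow(points)
  if (n < 3L) stop("ordinary kriging needs at least 3 points")
  vg <- variogram
  if (!(vg$range > 0 && vg$sill > vg$nugget && vg$nugget >= 0))
    stop("variogram must satisfy range > 0, sill > nugget >= 0")
  xy <- as.matrix(points[, c("x", "y")])
  Dp <- as.matrix(stats::dist(xy))
  if (any(Dp[upper.tri(Dp)] == 0))
    stop("duplicate point locations make the kriging system singular")
  A <- matrix(1, n + 1L, n + 1L)
  A[1:n, 1:n] <- spherical_semivariance(Dp, vg$nugget, vg$sill, vg$range)
  A[n + 1L, n + 1L] <- 0

  if (inherits(targets, "raster_grid")) {
    cc <- cell_centers(targets)
    tx <- rep(cc$x, each = targets$nrows)
    ty <- rep(cc$y, times = targets$ncols)
    tcoord <- cbind(tx, ty)
  } else {
    tcoord <- as.matrix(targets)[, 1:2, drop = FALSE]
  }
  m <- nrow(tcoord)
  Dt <- sqrt(outer(tcoord[, 1], xy[, 1], "-")^2 +
             outer(tcoord[, 2], xy[, 2], "-")^2)
  B <- rbind(t(spherical_semivariance(Dt, vg$nugget, vg$sill, vg$range)),
             rep(1, m))
  W <- solve(A, B)
  pred <- drop(crossprod(W[1:n, , drop = FALSE], points$value))
  if (inherits(targets, "raster_grid")) {
    out <- raster_grid(matrix(pred, targets$nrows, targets$ncols),
                       targets$origin, targets$cell_size, targets$crs_label)
  } else {
    out <- pred
  }
  attr(out, "weights") <- t(W[1:n, , drop = FALSE])
  out
}

#' Fit a spherical variogram by weighted least squares
#'
#' Empirical semivariogram on distance bins (default 12 bins up to half the
#' maximum pairwise distance), then a pair-count-weighted least-squares fit
#' of the spherical model via box-constrained optimization.
#'
#' @param points data frame with `x`, `y`, `value` (>= 10 rows).
#' @param n_bins number of distance bins.
#' @return list `nugget`, `sill`, `range`, `degenerate` plus the empirical
#'   bins (`bin_h`, `bin_gamma`, `bin_n`). A constant field returns the
#'   degenerate flag with `nugget = 0` and a tiny sill.
#' @export
fit_spherical_variogram <- function(points, n_bins = 12L) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "value") %in% names(points)))
  if (nrow(points) < 10L) stop("variogram fitting needs at least 10 points")
  z <- points$value
  if (stats::sd(z) == 0)
    return(list(nugget = 0, sill = 1e-12, range = 1e-12, degenerate = TRUE,
                bin_h = numeric(0), bin_gamma = numeric(0), bin_n = integer(0)))
  d <- stats::dist(points[, c("x", "y")])
  dz2 <- 0.5 * stats::dist(z)^2
  hmax <- max(d) / 2
  keep <- d <= hmax
  bins <- cut(as.numeric(d)[keep], breaks = seq(0, hmax, length.out = n_bins + 1L),
              include.lowest = TRUE)
  gb <- tapply(as.numeric(dz2)[keep], bins, mean)
  hb <- tapply(as.numeric(d)[keep], bins, mean)
  nb <- tapply(rep(1L, sum(keep)), bins, sum)
  ok <- !is.na(gb)
  gb <- gb[ok]; hb <- hb[ok]; nb <- nb[ok]
  s2 <- stats::var(z)
  obj <- function(par) {
    g <- spherical_semivariance(hb, par[1], par[1] + par[2], par[3])
    sum(nb * (gb - g)^2)
  }
  init <- c(max(min(gb), 1e-8), max(s2 - min(gb), 1e-8), hmax / 2)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-10, hmax * 1e-4),
                      upper = c(Inf, Inf, hmax * 10))
  list(nugget = fit$par[1], sill = fit$par[1] + fit$par[2],
       range = fit$par[3], degenerate = FALSE,
       bin_h = unname(hb), bin_gamma = unname(gb), bin_n = unname(nb))
}

#' Bilinear resampling onto a new grid
#'
#' Each destination cell center is interpolated among the four surrounding
#' source cell centers; destination centers outside the source center
#' lattice, or with any nodata corner, become nodata (counted in attribute
#' `"n_outside"`).
#'
#' @param src a `raster_grid`.
#' @param dst_spec target geometry, e.g. from [grid_spec()].
#' @return a `raster_grid` on `dst_spec`'s geometry.
#' @export
bilinear_resample <- function(src, dst_spec) {
  cs <- cell_centers(src)
  cd <- cell_centers(dst_spec)
  # continuous (row, col) position of dst centers in the src center lattice
  gx <- (cd$x - cs$x[1]) / src$cell_size + 1
  gy <- (cs$y[1] - cd$y) / src$cell_size + 1
  out <- matrix(NA_real_, dst_spec$nrows, dst_spec$ncols)
  n_outside <- 0L
  j0 <- floor(gx); fx <- gx - j0
  i0 <- floor(gy); fy <- gy - i0
  # a dst center sitting exactly on the last src center is still inside
  snap_j <- j0 == src$ncols & fx < 1e-9
  j0[snap_j] <- src$ncols - 1L; fx[snap_j] <- 1
  snap_i <- i0 == src$nrows & fy < 1e-9
  i0[snap_i] <- src$nrows - 1L; fy[snap_i] <- 1
  for (i in seq_len(dst_spec$nrows)) {
    ii <- i0[i]
    if (is.na(ii) || ii < 1L || ii + 1L > src$nrows) {
      n_outside <- n_outside + dst_spec$ncols
      next
    }
    jok <- which(j0 >= 1L & j0 + 1L <= src$ncols)
    n_outside <- n_outside + (dst_spec$ncols - length(jok))
    if (!length(jok)) next
    v00 <- src$values[ii, j0[jok]]
    v01 <- src$values[ii, j0[jok] + 1L]
    v10 <- src$values[ii + 1L, j0[jok]]
    v11 <- src$values[ii + 1L, j0[jok] + 1L]
    out[i, jok] <- (1 - fy[i]) * ((1 - fx[jok]) * v00 + fx[jok] * v01) +
      fy[i] * ((1 - fx[jok]) * v10 + fx[jok] * v11)
  }
  res <- raster_grid(out, dst_spec$origin, dst_spec$cell_size, src$crs_label)
  attr(res, "n_outside") <- n_outside
  res
}

#' Extract raster values at station locations
#'
#' Nearest-cell lookup. Stations falling outside the grid or on nodata are
#' reported in the removal log rather than raising an error; the working
#' station set is expected to drop them (see [attach_grid_covariates()]).
#'
#' @param grid a `raster_grid`.
#' @param stations a [station_set()].
#' @return list with `values` (length n, `NA` where dropped), `kept`
#'   (logical) and `dropped` (station ids).
#' @export
extract_at_stations <- function(grid, stations) {
  col <- floor((stations$x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((grid$origin[2] - stations$y) / grid$cell_size) + 1L
  inside <- col >= 1L & col <= grid$ncols & row >= 1L & row <= grid$nrows
  v <- rep(NA_real_, length(col))
  v[inside] <- grid$values[cbind(row[inside], col[inside])]
  kept <- inside & is.finite(v)
  list(values = v, kept = kept, dropped = stations$station_id[!kept])
}

#' Build station covariates from a raster stack
#'
#' Extracts every layer at the station locations and drops stations hitting
#' nodata in any layer, logging the removals (attribute `"removal_log"`).
#'
#' @param stations a [station_set()] (existing covariates are replaced).
#' @param stack named list of aligned `raster_grid`s.
#' @return a new [station_set()].
#' @export
attach_grid_covariates <- function(stations, stack) {
  stopifnot(length(names(stack)) == length(stack), !anyDuplicated(names(stack)))
  ext <- lapply(stack, extract_at_stations, stations = stations)
  M <- do.call(cbind, lapply(ext, `[[`, "values"))
  colnames(M) <- names(stack)
  kept <- Reduce(`&`, lapply(ext, `[[`, "kept"))
  out <- station_set(stations$station_id[kept], stations$x[kept],
                     stations$y[kept], stations$value[kept],
                     M[kept, , drop = FALSE])
  attr(out, "removal_log") <- stations$station_id[!kept]
  out
}

#' Predict an exposure map from a fitted model
#'
#' For every valid grid cell: standardize the covariates with the model's
#' stored (mean, sd), extend each selected eigenvector to the cell center by
#' [nystrom_extend()] using the training kernel and range, evaluate the
#' model, and back-transform to the raw response scale. The spatial-filter
#' surface (the fitted eigenvector combination) is returned on the
#' standardized-response scale so maps are comparable across periods.
#'
#' @param model an `esfr_model`.
#' @param stack named list of aligned `raster_grid` covariates covering the
#'   model's covariate names.
#' @param weights the training [spatial_weights()] (kernel and range).
#' @param basis the training [eigen_basis()].
#' @param stations the training [station_set()] (locations for the kernel
#'   rows).
#' @param standard concentration standard for level classification.
#' @param multipliers level cut multipliers, default `c(1, 1.5, 2)`.
#' @return object of class `exposure_grid`: `prediction`, `filter_surface`,
#'   `levels`, `area_pct`, `mean_map`, `mean_stations`.
#' @export
predict_map <- function(model, stack, weights, basis, stations,
                        standard = 35, multipliers = c(1, 1.5, 2)) {
  stopifnot(inherits(model, "esfr_model"), inherits(weights, "spatial_weights"),
            inherits(basis, "eigen_basis"), inherits(stations, "station_set"))
  ref <- stack[[1L]]
  for (g in stack) if (!.same_grid(ref, g))
    stop("covariate stack is not aligned to a single grid geometry")
  miss <- setdiff(model$covariate_names, names(stack))
  if (length(miss)) stop("stack lacks model covariates: ",
                         paste(miss, collapse = ", "))
  nr <- ref$nrows; nc <- ref$ncols
  layer_vals <- vapply(model$covariate_names,
                       function(nm) as.vector(stack[[nm]]$values),
                       numeric(nr * nc))
  layer_vals <- matrix(layer_vals, nrow = nr * nc,
                       dimnames = list(NULL, model$covariate_names))
  valid <- if (ncol(layer_vals)) apply(is.finite(layer_vals), 1L, all)
           else rep(TRUE, nr * nc)
  if (!any(valid)) stop("no valid cells in the covariate stack")
  cc <- cell_centers(ref)
  cx <- rep(cc$x, each = nr)[valid]
  cy <- rep(cc$y, times = nc)[valid]

  ev <- NULL
  filt_std <- rep(0, sum(valid))
  if (length(model$eigen_indices)) {
    Dts <- sqrt(outer(cx, stations$x, "-")^2 + outer(cy, stations$y, "-")^2)
    K <- exp(-Dts / weights$r)
    ev <- nystrom_extend(basis, weights$C0, K, model$eigen_indices)
    ev <- matrix(ev, ncol = length(model$eigen_indices))
    for (j in seq_along(model$eigen_indices)) {
      nm <- paste0("EV", model$eigen_indices[j])
      s <- model$standardization$columns[[nm]]
      filt_std <- filt_std +
        model$alpha[[nm]] * (ev[, j] - s[["mean"]]) / s[["sd"]]
    }
  }
  pred <- predict(model, layer_vals[valid, , drop = FALSE], ev)

  pv <- rep(NA_real_, nr * nc); pv[valid] <- pred
  fv <- rep(NA_real_, nr * nc); fv[valid] <- filt_std
  prediction <- raster_grid(matrix(pv, nr, nc), ref$origin, ref$cell_size,
                            ref$crs_label)
  filter_surface <- raster_grid(matrix(fv, nr, nc), ref$origin, ref$cell_size,
                                ref$crs_label)
  cl <- classify_levels(prediction, standard, multipliers)
  structure(list(prediction = prediction, filter_surface = filter_surface,
                 levels = cl$levels, area_pct = cl$area_pct,
                 mean_map = mean(pred), mean_stations = mean(stations$value)),
            class = "exposure_grid")
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat(sprintf("exposure_grid: map mean %.2f (stations %.2f)\n",
              x$mean_map, x$mean_stations))
  cat("  area %% by level: ",
      paste(sprintf("L%s %.1f", names(x$area_pct), x$area_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Classify a prediction grid into standard-relative levels
#'
#' Level 1: v <= standard; level 2: up to 1.5x; level 3: up to 2x; level 4:
#' above twice the standard. Boundary values belong to the lower level.
#' Area percentages are over valid cells (each cell has equal area).
#'
#' @param prediction a `raster_grid`.
#' @param standard the concentration standard (default 35).
#' @param multipliers cut multipliers, default `c(1, 1.5, 2)`.
#' @return list with `levels` (a `raster_grid` of 1-4) and `area_pct`
#'   (named numeric summing to 100 over levels present).
#' @export
classify_levels <- function(prediction, standard = 35,
                            multipliers = c(1, 1.5, 2)) {
  stopifnot(standard > 0, length(multipliers) == 3L)
  v <- prediction$values
  valid <- is.finite(v)
  if (!any(valid)) stop("no valid cells to classify")
  cuts <- standard * multipliers
  lev <- 1 + (v > cuts[1]) + (v > cuts[2]) + (v > cuts[3])
  lev[!valid] <- NA_real_
  counts <- tabulate(lev[valid], nbins = 4L)
  area_pct <- 100 * counts / sum(valid)
  names(area_pct) <- as.character(1:4)
  list(levels = raster_grid(lev, prediction$origin, prediction$cell_size,
                            prediction$crs_label),
       area_pct = area_pct)
}
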