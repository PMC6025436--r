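test_that("ordinary kriging: exactness, unbiasedness and the dense-solve oracle", {
  pts <- data.frame(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10),
                    value = c(1, 3, 2, 5))
  vg <- list(nugget = 0, sill = 2, range = 15)
  # exact interpolation at a data point with zero nugget
  at_pt <- ordinary_kriging(pts, vg, cbind(10, 0))
  expect_equal(as.numeric(at_pt), 3, tolerance = 1e-9)

  # weights sum to one at arbitrary targets
  tg <- cbind(c(2.5, 7.1, 4.4), c(8.2, 1.3, 5.5))
  pr <- ordinary_kriging(pts, vg, tg)
  W <- attr(pr, "weights")
  expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-8)

  # independent augmented-system solve for one target
  g <- function(h) ifelse(h == 0, 0,
    ifelse(h <= vg$range,
           vg$nugget + (vg$sill - vg$nugget) *
             (1.5 * h / vg$range - 0.5 * (h / vg$range)^3),
           vg$sill))
  xy <- as.matrix(pts[, 1:2])
  A <- rbind(cbind(g(as.matrix(dist(xy))), 1), c(1, 1, 1, 1, 0))
  t1 <- c(3, 4)
  b <- c(g(sqrt(colSums((t(xy) - t1)^2))), 1)
  wsol <- solve(A, b)
  or <- sum(wsol[1:4] * pts$value)
  expect_equal(as.numeric(ordinary_kriging(pts, vg, rbind(t1))), or,
               tolerance = 1e-10)

  # constant field predicts the constant everywhere
  ptsc <- transform(pts, value = 7)
  grd <- grid_spec(c(-5, 15), 5, 4, 4)
  prc <- ordinary_kriging(ptsc, vg, grd)
  expect_equal(as.vector(prc$values), rep(7, 16), tolerance = 1e-9)

  expect_error(ordinary_kriging(pts[c(1, 1, 2), ], vg, tg), "duplicate")
  expect_error(ordinary_kriging(pts[1:2, ], vg, tg), "at least 3")
})

test_that("spherical variogram fit recovers simulated parameters", {
  true <- list(nugget = 0.2, sill = 1.2, range = 30)
  nrep <- 5
  sills <- ranges <- numeric(nrep)
  for (k in seq_len(nrep)) {
    set.seed(100 + k)
    n <- 150
    xy <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    h <- as.matrix(dist(xy))
    Cv <- true$sill - spherical_semivariance(h, true$nugget, true$sill,
                                             true$range)
    z <- drop(chol(Cv + diag(1e-8, n)) %*% rnorm(n))
    fit <- fit_spherical_variogram(data.frame(x = xy[, 1], y = xy[, 2],
                                              value = z))
    sills[k] <- fit$sill; ranges[k] <- fit$range
  }
  expect_lt(abs(mean(sills) - true$sill) / true$sill, 0.3)
  expect_lt(abs(mean(ranges) - true$range) / true$range, 0.3)

  # iid values: flat variogram, fitted sill near the variance
  set.seed(111)
  z <- rnorm(200, 0, 2)
  fit0 <- fit_spherical_variogram(data.frame(x = runif(200, 0, 50),
                                             y = runif(200, 0, 50), value = z))
  expect_lt(abs(fit0$sill - var(z)) / var(z), 0.25)

  # constant field degenerates gracefully
  fitc <- fit_spherical_variogram(data.frame(x = 1:12, y = (1:12)^1.3,
                                             value = rep(4, 12)))
  expect_true(fitc$degenerate)
  expect_equal(fitc$nugget, 0)
})

test_that("bilinear resampling: node identity, midpoint, direct formula, bounds", {
  src <- raster_grid(matrix(c(1, 3, 2, 4), 2, 2, byrow = TRUE), c(0, 2), 1)
  # dst aligned with src centers -> exact copy
  same <- bilinear_resample(src, grid_spec(c(0, 2), 1, 2, 2))
  expect_equal(same$values, src$values)
  # midpoint of the 4 centers
  mid <- bilinear_resample(src, grid_spec(c(0.5, 1.5), 1, 1, 1))
  expect_equal(mid$values[1, 1], 2.5)

  set.seed(120)
  sv <- matrix(runif(64), 8, 8)
  src8 <- raster_grid(sv, c(0, 8), 1)
  dst <- grid_spec(c(1.13, 6.77), 0.83, 5, 5)
  out <- bilinear_resample(src8, dst)
  cc_s <- cell_centers(src8); cc_d <- cell_centers(dst)
  for (i in 1:5) for (j in 1:5) {
    gx <- (cc_d$x[j] - cc_s$x[1]) / 1 + 1
    gy <- (cc_s$y[1] - cc_d$y[i]) / 1 + 1
    j0 <- floor(gx); i0 <- floor(gy); fx <- gx - j0; fy <- gy - i0
    v <- (1 - fy) * ((1 - fx) * sv[i0, j0] + fx * sv[i0, j0 + 1]) +
      fy * ((1 - fx) * sv[i0 + 1, j0] + fx * sv[i0 + 1, j0 + 1])
    expect_equal(out$values[i, j], v, tolerance = 1e-12)
  }
  ok <- is.finite(out$values)
  expect_gte(min(out$values[ok]), min(sv))
  expect_lte(max(out$values[ok]), max(sv))

  # fully outside -> nodata, counted
  far <- bilinear_resample(src8, grid_spec(c(100, 200), 1, 3, 3))
  expect_true(all(is.na(far$values)))
  expect_equal(attr(far, "n_outside"), 9L)

  # nodata corner propagates
  sv2 <- sv; sv2[4, 4] <- NA
  out2 <- bilinear_resample(raster_grid(sv2, c(0, 8), 1),
                            grid_spec(c(2.6, 5.4), 1, 2, 2))
  expect_true(any(is.na(out2$values)))
})

test_that("extract_at_stations uses nearest-cell arithmetic and drops nodata", {
  v <- matrix(1:12, 3, 4)
  v[2, 3] <- NA
  g <- raster_grid(v, c(0, 30), 10)  # cells 10 km, origin top-left (0, 30)
  s <- station_set(1:5,
                   x = c(5, 25, 25, 38, 55),
                   y = c(25, 15, 25, 2, 10),
                   value = 1:5)
  ex <- extract_at_stations(g, s)
  # manual floor((x - x0)/cell) arithmetic
  expect_equal(ex$values[1], v[1, 1])
  expect_equal(ex$values[3], v[1, 3])
  expect_true(is.na(ex$values[2]))           # lands on the NA cell
  expect_equal(ex$values[4], v[3, 4])
  expect_true(is.na(ex$values[5]))           # outside the grid
  expect_equal(ex$dropped, c("2", "5"))

  stack <- list(A = g, B = raster_grid(matrix(2, 3, 4), c(0, 30), 10))
  s2 <- attach_grid_covariates(s, stack)
  expect_equal(n_stations(s2), 3L)
  expect_equal(attr(s2, "removal_log"), c("2", "5"))
  expect_equal(unname(s2$covariates[, "B"]), rep(2, 3))
})

test_that("classify_levels respects the boundary convention and sums to 100", {
  g <- raster_grid(matrix(c(35, 52.5, 70.0001, 10, 40, 60, 80, NA), 2, 4),
                   c(0, 2), 1)
  cl <- classify_levels(g)
  expect_equal(cl$levels$values[1, 1], 1)   # v = 35 -> level 1
  expect_equal(cl$levels$values[2, 1], 2)   # v = 52.5 -> level 2
  expect_equal(cl$levels$values[1, 2], 4)   # v = 70.0001 -> level 4
  expect_true(is.na(cl$levels$values[2, 4]))
  expect_equal(sum(cl$area_pct), 100, tolerance = 0.1)

  g4 <- raster_grid(matrix(c(10, 40, 60, 80), 2, 2), c(0, 2), 1)
  expect_equal(unname(classify_levels(g4)$area_pct), rep(25, 4))
  expect_error(classify_levels(raster_grid(matrix(NA_real_, 2, 2), c(0, 2), 1)),
               "no valid cells")
})

test_that("predict_map matches a scalar per-cell recomputation", {
  cfg <- sim_config(seed = 130, n_stations = 50, region = c(0, 100, 0, 80))
  scene <- simulate_scene(cfg, cell_size = 5)
  m <- fit_esfr(scene$stations, weights = scene$weights, basis = scene$basis)
  w <- scene$weights
  eg <- predict_map(m, scene$rasters, w, scene$basis, scene$stations)

  expect_equal(sum(eg$area_pct), 100, tolerance = 0.1)
  ref <- scene$rasters[[1]]
  cc <- cell_centers(ref)
  set.seed(131)
  cells <- cbind(sample(ref$nrows, 6), sample(ref$ncols, 6))
  stn <- scene$stations
  for (k in 1:6) {
    i <- cells[k, 1]; j <- cells[k, 2]
    acc <- m$intercept
    for (nm in m$covariate_names) {
      s <- m$standardization$columns[[nm]]
      acc <- acc + m$beta[[nm]] *
        (scene$rasters[[nm]]$values[i, j] - s[["mean"]]) / s[["sd"]]
    }
    filt <- 0
    for (idx in m$eigen_indices) {
      d <- sqrt((stn$x - cc$x[j])^2 + (stn$y - cc$y[i])^2)
      krow <- exp(-d / w$r)
      ct <- krow - mean(krow) - colMeans(w$C0) + mean(w$C0)
      ev <- sum(ct * scene$basis$vectors[, idx]) / scene$basis$values[idx]
      s <- m$standardization$columns[[paste0("EV", idx)]]
      contrib <- m$alpha[[paste0("EV", idx)]] * (ev - s[["mean"]]) / s[["sd"]]
      acc <- acc + contrib
      filt <- filt + contrib
    }
    r <- m$standardization$response
    expect_equal(eg$prediction$values[i, j], r[["mean"]] + r[["sd"]] * acc,
                 tolerance = 1e-8)
    expect_equal(eg$filter_surface$values[i, j], filt, tolerance = 1e-8)
  }

  # model without eigenvectors -> identically zero filter surface
  g0 <- fit_gmlr(stn$value, stn$covariates)
  eg0 <- predict_map(g0, scene$rasters, w, scene$basis, stn)
  expect_equal(max(abs(eg0$filter_surface$values)), 0)

  # translation equivariance of the whole map
  sh <- c(250, -40)
  stn2 <- station_set(stn$station_id, stn$x + sh[1], stn$y + sh[2],
                      stn$value, stn$covariates)
  w2 <- spatial_weights(stn2)
  b2 <- eigen_basis(w2$C1)
  m2 <- fit_esfr(stn2, weights = w2, basis = b2)
  stack2 <- lapply(scene$rasters, function(g)
    raster_grid(g$values, g$origin + sh, g$cell_size))
  eg2 <- predict_map(m2, stack2, w2, b2, stn2)
  expect_equal(eg2$prediction$values, eg$prediction$values, tolerance = 1e-6)
})

test_that("ascii grid round-trips and misaligned stacks are rejected", {
  set.seed(140)
  g <- raster_grid(matrix(rnorm(20), 4, 5), c(3.5, 42), 2.5)
  g$values[2, 2] <- NA
  p <- file.path(tempdir(), "t.asc")
  write_ascii_grid(g, p)
  g2 <- read_ascii_grid(p)
  expect_equal(g2$values, g$values, tolerance = 1e-9)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$cell_size, g$cell_size)

  scene <- quick_scene(141, n = 30)
  m <- fit_gmlr(scene$stations$value, scene$stations$covariates)
  stack <- list(AOD = g, ST = raster_grid(matrix(1, 4, 5), c(0, 42), 2.5))
  expect_error(predict_map(m, stack, spatial_weights(scene$stations),
                           eigen_basis(spatial_weights(scene$stations)$C1),
                           scene$stations),
               "not aligned")
})
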