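test_that("generators are pure functions of the configuration", {
  cfg <- sim_config(seed = 200, n_stations = 40, region = c(0, 120, 0, 90))
  s1 <- simulate_scene(cfg, cell_size = 15)
  s2 <- simulate_scene(cfg, cell_size = 15)
  expect_identical(s1$stations$x, s2$stations$x)
  expect_identical(s1$stations$value, s2$stations$value)
  expect_identical(s1$rasters$AOD$values, s2$rasters$AOD$values)
  expect_identical(s1$sources$factories, s2$sources$factories)
  expect_identical(s1$sources$roads, s2$sources$roads)

  # a different seed changes the draw
  s3 <- simulate_scene(sim_config(seed = 201, n_stations = 40,
                                  region = c(0, 120, 0, 90)), cell_size = 15)
  expect_false(identical(s1$stations$x, s3$stations$x))
})

test_that("gen_stations respects bounds and minimum separation", {
  cfg <- sim_config(seed = 202, n_stations = 80, region = c(10, 60, -20, 20))
  s <- gen_stations(cfg)
  expect_true(all(s$x >= 10 & s$x <= 60))
  expect_true(all(s$y >= -20 & s$y <= 20))
  D <- pairwise_distances(s)
  min_sep <- 0.001 * sqrt(50^2 + 40^2)
  expect_gte(min(D[upper.tri(D)]), min_sep)
})

test_that("covariate fields hit their configured moments", {
  cfg <- sim_config(seed = 203, n_stations = 20, region = c(0, 300, 0, 200))
  spec <- grid_spec(c(0, 200), 10, 20, 30)
  f <- gen_covariate_fields(cfg, spec)
  cm <- cfg$covariate_model
  for (i in seq_len(nrow(cm))) {
    v <- as.vector(f$rasters[[cm$name[i]]]$values)
    # integer-frequency modes nearly cancel over the lattice
    expect_lt(abs(mean(v) - cm$mean[i]), 0.15 * cm$sd[i] + 1e-9)
    expect_lt(abs(sd(v) - cm$sd[i]) / cm$sd[i], 0.35)
  }

  # zero-sd covariate gives a constant raster
  cm0 <- cm; cm0$sd[1] <- 0
  cfg0 <- sim_config(seed = 204, n_stations = 20, covariate_model = cm0)
  f0 <- gen_covariate_fields(cfg0, spec)
  expect_equal(max(f0$rasters$AOD$values), min(f0$rasters$AOD$values))
})

test_that("gen_response realizes the stated linear model", {
  scene <- quick_scene(205, n = 80)
  tr <- scene$truth
  # deterministic skeleton: subtracting the known parts leaves N(0, sigma)
  X <- scene$stations$covariates[, names(tr$beta_raw)]
  eps <- scene$stations$value - tr$beta0 - drop(X %*% tr$beta_raw) -
    drop(scene$basis$vectors[, tr$eigen_indices] %*% tr$alpha)
  expect_lt(abs(sd(eps) - tr$sigma) / tr$sigma, 0.5)
  expect_lt(abs(mean(eps)), 3 * tr$sigma / sqrt(80))

  # noiseless, filter-free data recover beta exactly
  cfgn <- sim_config(seed = 206, n_stations = 50, k_true = 0L,
                     alpha_true = numeric(0),
                     true_eigen_indices = integer(0), sigma = 0)
  sn <- simulate_scene(cfgn, rasters = FALSE)
  g <- fit_gmlr(sn$stations$value, sn$stations$covariates)
  expect_lt(max(abs(g$residuals)), 1e-8)
  expect_equal(unname(g$beta[names(sn$truth$beta_std)]),
               unname(true_standardized_beta(sn$truth, sn$stations)),
               tolerance = 1e-6)

  # alpha on a non-candidate index is rejected
  cfg_bad <- sim_config(seed = 207, n_stations = 30, k_true = 1L,
                        true_eigen_indices = 29L, alpha_true = 5)
  expect_error(simulate_scene(cfg_bad, rasters = FALSE),
               "outside the candidate set")
})

test_that("a dominant filter eigenvector is picked first by stepwise", {
  hits <- 0L
  for (seed in 301:320) {
    cfg <- sim_config(seed = seed, n_stations = 80, k_true = 1L,
                      true_eigen_indices = 2L, alpha_true = 80,
                      region = c(0, 200, 0, 150))
    sc <- simulate_scene(cfg, rasters = FALSE)
    sel <- forward_stepwise_eigen(sc$stations$value, sc$stations$covariates,
                                  select_candidates(sc$basis), sc$basis)
    if (length(sel) && sel[1] == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90% of replicates
})

test_that("variance decomposition holds across replicates", {
  nrep <- 30
  vy <- numeric(nrep)
  cfg0 <- sim_config(seed = 1, n_stations = 120)
  for (k in seq_len(nrep)) {
    sc <- quick_scene(400 + k, n = 120)
    vy[k] <- var(sc$stations$value)
  }
  cfg <- sim_config(seed = 1, n_stations = 120)
  expected <- cfg$response_sd^2 * sum(cfg$beta_std_true^2) +
    sum(cfg$alpha_true^2) / 120 + cfg$sigma^2
  # Monte-Carlo tolerance: covariate fields are finite samples, so allow 15%
  expect_lt(abs(mean(vy) - expected) / expected, 0.15)
})

test_that("gen_sources honors counts and empty sets propagate", {
  cfg <- sim_config(seed = 208, n_stations = 20, n_factories = 17L,
                    n_roads = 4L)
  src <- gen_sources(cfg)
  expect_equal(nrow(src$factories), 17L)
  expect_length(src$roads, 4L)
  expect_true(all(vapply(src$roads, nrow, integer(1)) == 21L))

  cfg0 <- sim_config(seed = 209, n_stations = 20, n_factories = 0L)
  src0 <- gen_sources(cfg0)
  pd <- point_density(src0$factories, grid_spec(c(0, 100), 25, 4, 4), 24)
  expect_equal(pd$values, matrix(0, 4, 4))
})
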