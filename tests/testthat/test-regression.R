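test_that("fit_ols: perfect fit, null model, normal-equations oracle", {
  set.seed(1)
  x <- rnorm(30)
  y <- 3 + 2 * x
  m <- fit_ols(y, cbind(a = x))
  expect_equal(m$fit$r2_adj, 1, tolerance = 1e-12)
  expect_lt(m$fit$rse, 1e-10)
  expect_lt(max(abs(m$residuals)), 1e-10)
  expect_equal(unname(m$beta[["a"]]), 1, tolerance = 1e-10)  # standardized

  set.seed(2)
  n <- 4000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y0 <- rnorm(n)
  m0 <- fit_ols(y0, X)
  expect_lt(max(abs(m0$beta)), 0.05)
  expect_lt(abs(m0$fit$r2_adj), 0.01)

  # 10-point fixture against an independent normal-equations solve on the
  # standardized scale
  set.seed(3)
  X10 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("u", "v")))
  y10 <- rnorm(10, 5, 2)
  m10 <- fit_ols(y10, X10)
  Z <- scale(X10); yz <- as.vector(scale(y10))
  A <- cbind(1, Z)
  coef_or <- solve(crossprod(A), crossprod(A, yz))
  expect_equal(unname(m10$beta), unname(coef_or[2:3]), tolerance = 1e-10)
  expect_equal(m10$intercept, unname(coef_or[1]), tolerance = 1e-10)
  # metrics from their definitions
  res <- y10 - m10$fitted
  expect_equal(m10$fit$rse, sqrt(sum(res^2) / (10 - 2 - 1)))
  expect_equal(m10$fit$mape, 100 * mean(abs(res) / abs(y10)))
  r2 <- 1 - sum(res^2) / sum((y10 - mean(y10))^2)
  expect_equal(m10$fit$r2_adj, 1 - (1 - r2) * 9 / 7)
})

test_that("fit_ols flags rank deficiency, zero response values and constants", {
  set.seed(4)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x, c = rnorm(20))
  expect_error(fit_ols(rnorm(20), X), "collinear")
  expect_error(fit_ols(rnorm(20), cbind(k = rep(1, 20), x = x)), "constant")
  y <- rnorm(20); y[5] <- 0
  m <- fit_ols(y, cbind(a = x))
  expect_true(is.na(m$fit$mape))  # undefined, not infinite
})

test_that("AICc approaches AIC for large n", {
  set.seed(5)
  n <- 1e5
  X <- matrix(rnorm(5 * n), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X %*% rep(0.2, 5) + rnorm(n)
  m <- fit_ols(y, X[, 1:3])  # p = 3, k = 5
  rss <- sum(m$residuals^2)
  k <- 3 + 2
  aic <- n * log(2 * pi) + n * log(rss / n) + n + 2 * k
  expect_lt(abs(m$fit$aicc - aic), 1e-3)
})

test_that("standardized coefficients are invariant to covariate rescaling", {
  s <- quick_scene(31)
  m1 <- fit_gmlr(s$stations$value, s$stations$covariates)
  X2 <- s$stations$covariates
  X2[, "PBLH"] <- X2[, "PBLH"] * 1000
  m2 <- fit_gmlr(s$stations$value, X2)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-8)
})

test_that("forward stepwise finds an injected eigenvector and stops on noise", {
  scene <- quick_scene(8, n = 150)
  b <- scene$basis
  cand <- select_candidates(b)
  X <- scene$stations$covariates
  set.seed(80)
  # strong signal solely on eigenvector 3
  y3 <- 50 + 30 * b$vectors[, 3] + rnorm(150, 0, 1)
  sel <- forward_stepwise_eigen(y3, X, cand, b)
  expect_equal(sel[1], 3L)

  # no spatial signal: a few candidates still clear the adjusted-R^2 bar by
  # chance (greedy max over ~25 candidates), but the selection stays small
  # and the fit close to GMLR's
  yns <- 50 + X %*% rnorm(ncol(X), 0, 0.002) + rnorm(150, 0, 5)
  sel2 <- forward_stepwise_eigen(yns, X, cand, b)
  g <- fit_gmlr(yns, X)
  m <- fit_ols(yns, X, b$vectors[, sel2, drop = FALSE], sel2)
  expect_lte(length(sel2), 12)
  expect_lte(abs(m$fit$r2_adj - g$fit$r2_adj), 0.10)

  # nesting: adding eigenvectors never lowers plain R^2
  expect_gte(m$fit$r2 + 1e-12, g$fit$r2)
  expect_gte(m$fit$r2_adj, g$fit$r2_adj - 0.01)
})

test_that("stepwise agrees with a brute-force refit implementation", {
  scene <- quick_scene(12, n = 50)
  b <- scene$basis
  cand <- select_candidates(b)
  y <- scene$stations$value
  X <- scene$stations$covariates
  sel <- forward_stepwise_eigen(y, X, cand, b)
  # independent greedy using full lm() fits at every step
  adj <- function(idx) {
    df <- data.frame(y = y, X, b$vectors[, idx, drop = FALSE])
    summary(stats::lm(y ~ ., data = df))$adj.r.squared
  }
  chosen <- integer(0)
  pool <- cand$indices
  repeat {
    cur <- adj(chosen)
    scores <- vapply(pool, function(j) adj(c(chosen, j)), numeric(1))
    if (!length(scores) || max(scores) <= cur) break
    j <- pool[which.max(scores)]
    chosen <- c(chosen, j)
    pool <- setdiff(pool, j)
  }
  expect_equal(sel, chosen)
})

test_that("prune_and_refit removes noise covariates and is idempotent-ish", {
  # vacuous threshold prunes nothing
  scene <- quick_scene(9, n = 80)
  m <- fit_esfr(scene$stations, prune = FALSE)
  m1 <- prune_and_refit(m, alpha_level = 1.0)
  expect_equal(m1$pruned, character(0))
  expect_equal(m1$covariate_names, m$covariate_names)

  # a pure-noise covariate appended to a strong model is pruned in >= 90%
  # of replicates (non-spatial fits keep this fast)
  set.seed(70)
  hits <- 0L
  n <- 300
  for (rep_ in 1:50) {
    X <- cbind(a = rnorm(n), b = rnorm(n), junk = rnorm(n))
    y <- 5 + 3 * X[, "a"] - 2 * X[, "b"] + rnorm(n)
    g <- fit_gmlr(y, X)
    attr(g, "training") <- list(y = y, covariates = X,
                                candidates = NULL, basis = NULL)
    g2 <- prune_and_refit(g, alpha_level = 0.10)
    if ("junk" %in% g2$pruned) hits <- hits + 1L
  }
  expect_gte(hits, 45L)

  # pruning everything still leaves a usable eigenvectors-only model
  scene2 <- quick_scene(13, n = 60)
  X <- scene2$stations$covariates
  Xn <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("n1", "n2")))
  b <- scene2$basis
  yy <- 40 + 25 * b$vectors[, 1] + rnorm(60, 0, 0.5)
  mm <- fit_ols(yy, Xn, b$vectors[, 1, drop = FALSE], 1L)
  attr(mm, "training") <- list(y = yy, covariates = Xn,
                               candidates = select_candidates(b), basis = b)
  expect_warning(m3 <- prune_and_refit(mm, alpha_level = 0.001),
                 "all covariates pruned")
  expect_length(m3$covariate_names, 0)
  expect_true(1L %in% m3$eigen_indices)
})

test_that("fit_gmlr is the eigen-free fit and percent_change matches the tables", {
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20, 10)
  expect_equal(fit_gmlr(y, X)$beta, fit_ols(y, X)$beta)

  expect_equal(percent_change(0.60, 0.70, "increase"), 16.7)
  expect_equal(percent_change(26.6, 18.9, "decrease"), 28.9)
  expect_equal(percent_change(5, 5, "increase"), 0.0)
  expect_error(percent_change(0, 1), "non-zero")
})

test_that("esfr model serializes with null markers for pruned covariates", {
  scene <- quick_scene(19, n = 70)
  m <- fit_esfr(scene$stations)
  js <- jsonlite::fromJSON(model_to_json(m), simplifyVector = FALSE)
  nm <- vapply(js$covariates, `[[`, character(1), "name")
  expect_setequal(nm, colnames(scene$stations$covariates))
  for (cv in js$covariates)
    if (cv$name %in% m$pruned) expect_null(cv$beta)
  expect_equal(length(js$eigen), length(m$eigen_indices))
})
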