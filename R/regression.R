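#' Ordinary least squares fit on standardized variables
#'
#' Fits the (possibly spatially filtered) linear model by OLS. The response
#' and every design column are z-scored with their sample mean and standard
#' deviation, so the reported coefficients are standardized "Beta" values;
#' the stored (mean, sd) pairs allow exact back-transformation, and all
#' error metrics (RSE, MAPE) are reported on the raw response scale.
#'
#' Fit metrics: adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1);
#' RSE = sqrt(RSS / (n - p - 1)); MAPE = (100/n) sum(|e_i| / |y_i|), flagged
#' undefined (NA) when any y_i = 0; AICc from the Gaussian log-likelihood
#' with ML variance and parameter count k = p + 2 (intercept + variance).
#'
#' @param y numeric response (raw scale).
#' @param covariates numeric matrix / data frame of named covariate columns
#'   (raw scale); may have zero columns.
#' @param eigenvectors optional matrix of eigenvector columns (one per entry
#'   of `eigen_indices`), as returned in an [eigen_basis()].
#' @param eigen_indices integer indices of the eigenvector columns.
#' @return object of class `esfr_model`: `covariate_names`, `eigen_indices`,
#'   `beta`, `alpha`, `intercept` (standardized scale), `pvalues`,
#'   `residuals`, `fitted` (raw scale), `fit` (list `r2`, `r2_adj`, `rse`,
#'   `mape`, `aicc`, `n`, `p`), `standardization`, `pruned`.
#' @export
fit_ols <- function(y, covariates, eigenvectors = NULL,
                    eigen_indices = integer(0)) {
  y <- as.numeric(y)
  n <- length(y)
  X_cov <- .as_design(covariates, n, "X")
  if (is.null(eigenvectors)) {
    X_eig <- matrix(numeric(0), n, 0)
  } else {
    X_eig <- as.matrix(eigenvectors)
    stopifnot(ncol(X_eig) == length(eigen_indices))
    colnames(X_eig) <- paste0("EV", eigen_indices)
  }
  X <- cbind(X_cov, X_eig)
  p <- ncol(X)
  if (n <= p + 2L)
    stop(sprintf("need n > p + 2 (n = %d, p = %d)", n, p))
  sdy <- stats::sd(y)
  if (sdy == 0) stop("response is constant")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant design column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  mus <- colMeans(X)
  Z <- sweep(sweep(X, 2, mus), 2, sds, "/")
  yz <- (y - mean(y)) / sdy

  Xf <- cbind(1, Z)
  qrx <- qr(Xf)
  if (qrx$rank < ncol(Xf)) {
    bad <- qrx$pivot[(qrx$rank + 1L):ncol(Xf)]
    stop("rank-deficient design; collinear columns: ",
         paste(c("(Intercept)", colnames(X))[bad], collapse = ", "))
  }
  coefz <- qr.coef(qrx, yz)
  fitted_z <- drop(Xf %*% coefz)
  res_z <- yz - fitted_z

  # inference on the standardized scale (p-values are scale invariant)
  XtXinv <- chol2inv(chol(crossprod(Xf)))
  sigma2_z <- sum(res_z^2) / (n - p - 1L)
  se <- sqrt(diag(XtXinv) * sigma2_z)
  tval <- coefz / se
  pval <- 2 * stats::pt(abs(tval), df = n - p - 1L, lower.tail = FALSE)

  fitted_raw <- mean(y) + sdy * fitted_z
  res_raw <- y - fitted_raw
  rss <- sum(res_raw^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  rse <- sqrt(rss / (n - p - 1))
  mape <- if (any(y == 0)) NA_real_ else 100 * mean(abs(res_raw) / abs(y))
  k <- p + 2
  aic <- n * log(2 * pi) + n * log(rss / n) + n + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_

  ncov <- ncol(X_cov)
  beta <- coefz[seq_len(ncov) + 1L]
  names(beta) <- colnames(X_cov)
  alpha <- if (ncol(X_eig)) coefz[(ncov + 2L):(p + 1L)] else numeric(0)
  names(alpha) <- colnames(X_eig)
  pv <- pval[-1L]; names(pv) <- colnames(X)

  std <- list(response = c(mean = mean(y), sd = sdy),
              columns = stats::setNames(
                lapply(seq_len(p), function(j)
                  c(mean = unname(mus[j]), sd = unname(sds[j]))),
                colnames(X)))
  structure(list(covariate_names = colnames(X_cov),
                 eigen_indices = as.integer(eigen_indices),
                 beta = beta, alpha = alpha, intercept = unname(coefz[1L]),
                 pvalues = pv, residuals = res_raw, fitted = fitted_raw,
                 fit = list(r2 = r2, r2_adj = r2_adj, rse = rse, mape = mape,
                            aicc = aicc, n = n, p = p),
                 standardization = std,
                 pruned = character(0)),
            class = "esfr_model")
}

.as_design <- function(x, n, what) {
  if (is.null(x)) return(matrix(numeric(0), n, 0))
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop(what, " must have one row per observation")
  if (ncol(X) && (is.null(colnames(X)) || anyDuplicated(colnames(X))))
    stop(what, " columns must have unique names")
  X
}

#' @export
print.esfr_model <- function(x, ...) {
  kind <- if (length(x$eigen_indices)) "ESFR" else "GMLR"
  cat(sprintf("%s model: n = %d, p = %d (%d covariates + %d eigenvectors)\n",
              kind, x$fit$n, x$fit$p, length(x$beta), length(x$alpha)))
  cat(sprintf("  adj R2 = %.3f, RSE = %.3f, MAPE = %s, AICc = %.1f\n",
              x$fit$r2_adj, x$fit$rse,
              ifelse(is.na(x$fit$mape), "undefined", sprintf("%.2f", x$fit$mape)),
              x$fit$aicc))
  if (length(x$pruned))
    cat("  pruned covariates: ", paste(x$pruned, collapse = ", "), "\n")
  invisible(x)
}

#' Non-spatial baseline (GMLR)
#'
#' Global multiple linear regression: the same OLS fit with no eigenvector
#' terms, used as the comparison baseline for the spatially filtered model.
#'
#' @inheritParams fit_ols
#' @return an `esfr_model` with empty `eigen_indices`.
#' @export
fit_gmlr <- function(y, covariates) fit_ols(y, covariates)

#' Forward stepwise selection of candidate eigenvectors
#'
#' All covariates are forced into the model; candidate eigenvectors are then
#' added one at a time, each round picking the candidate that maximizes
#' adjusted R^2, stopping when no addition improves it. Plain R^2 never
#' decreases under nesting, so the adjusted form supplies the stopping rule.
#' Implemented with incremental orthogonalization, so each candidate
#' evaluation costs O(n).
#'
#' @param y response vector.
#' @param covariates covariate matrix forced into every model (may be NULL).
#' @param candidates a [select_candidates()] result.
#' @param basis the [eigen_basis()] the candidates refer to.
#' @return integer vector of selected eigenvector indices, insertion order.
#' @export
forward_stepwise_eigen <- function(y, covariates, candidates, basis) {
  stopifnot(inherits(candidates, "candidate_set"),
            inherits(basis, "eigen_basis"))
  if (!length(candidates$indices)) stop("candidate set is empty")
  y <- as.numeric(y)
  n <- length(y)
  X0 <- cbind(1, .as_design(covariates, n, "X"))
  Q <- qr.Q(qr(X0))                       # orthonormal basis of forced columns
  yr <- y - Q %*% crossprod(Q, y)         # response residual
  rss <- sum(yr^2)
  tss <- sum((y - mean(y))^2)
  p_forced <- ncol(X0) - 1L
  adj <- function(rss, p) 1 - (rss / tss) * (n - 1) / (n - p - 1)
  cur_adj <- adj(rss, p_forced)

  remaining <- candidates$indices
  selected <- integer(0)
  Ecand <- basis$vectors[, remaining, drop = FALSE]
  # residualize candidates against forced columns (kept orthogonal as we go)
  Er <- Ecand - Q %*% crossprod(Q, Ecand)
  repeat {
    if (!length(remaining)) break
    nrm2 <- colSums(Er^2)
    ok <- nrm2 > 1e-10
    gain <- ifelse(ok, colSums(Er * as.vector(yr))^2 / nrm2, -Inf)
    cand_adj <- adj(rss - gain, p_forced + length(selected) + 1L)
    bst <- which.max(cand_adj)
    if (!ok[bst] || cand_adj[bst] <= cur_adj) break
    u <- Er[, bst] / sqrt(nrm2[bst])
    u <- u - Q %*% crossprod(Q, u)        # re-orthogonalize for stability
    u <- u / sqrt(sum(u^2))
    Q <- cbind(Q, u)
    yr <- yr - u * sum(u * yr)
    rss <- sum(yr^2)
    selected <- c(selected, remaining[bst])
    cur_adj <- cand_adj[bst]
    remaining <- remaining[-bst]
    Er <- Er[, -bst, drop = FALSE]
    if (length(remaining)) Er <- Er - u %*% crossprod(u, Er)
  }
  selected
}

#' Prune insignificant covariates and refit
#'
#' Removes covariates whose two-sided coefficient p-value exceeds
#' `alpha_level`, then re-runs eigenvector stepwise selection and OLS once
#' on the reduced covariate set. Removed covariates are recorded in
#' `$pruned` and rendered as "/" in report tables. If every covariate is
#' pruned the model proceeds with eigenvectors only, with a warning.
#'
#' @param model an `esfr_model` fitted by [fit_esfr()] or [fit_ols()] with
#'   training data attached (models from [fit_esfr()] carry it).
#' @param y,covariates,candidates,basis training data; taken from the model
#'   attributes when omitted.
#' @param alpha_level significance threshold, default 0.10.
#' @return refitted `esfr_model` with `$pruned` set.
#' @export
prune_and_refit <- function(model, alpha_level = 0.10, y = NULL,
                            covariates = NULL, candidates = NULL,
                            basis = NULL) {
  tr <- attr(model, "training")
  if (is.null(y)) y <- tr$y
  if (is.null(covariates)) covariates <- tr$covariates
  if (is.null(candidates)) candidates <- tr$candidates
  if (is.null(basis)) basis <- tr$basis
  if (is.null(y) || is.null(covariates))
    stop("training data not attached to model; pass y and covariates")
  covariates <- .as_design(covariates, length(y), "X")
  pv <- model$pvalues[model$covariate_names]
  keep <- model$covariate_names[pv <= alpha_level]
  pruned <- setdiff(model$covariate_names, keep)
  Xk <- covariates[, keep, drop = FALSE]
  if (!length(keep))
    warning("all covariates pruned; proceeding with eigenvectors only")
  if (!is.null(basis) && !is.null(candidates)) {
    sel <- forward_stepwise_eigen(y, if (length(keep)) Xk else NULL,
                                  candidates, basis)
    out <- fit_ols(y, Xk, basis$vectors[, sel, drop = FALSE], sel)
  } else {
    out <- fit_ols(y, Xk)
  }
  out$pruned <- pruned
  attr(out, "training") <- list(y = y, covariates = covariates,
                                candidates = candidates, basis = basis)
  out
}

#' Fit the full eigenvector spatial filtering regression
#'
#' Runs the five-step estimation procedure on a station set: (1) spatial
#' weights with MST-derived range, (2) eigendecomposition of the centered
#' weights, (3) forward stepwise eigenvector selection with all covariates,
#' (4) OLS estimation, (5) pruning of insignificant covariates followed by
#' one repetition of steps (3)-(4) on the reduced set.
#'
#' @param stations a [station_set()] with covariates.
#' @param weights optional precomputed [spatial_weights()].
#' @param basis optional precomputed [eigen_basis()].
#' @param threshold eigenvalue-ratio screening threshold (step 2), 0.10.
#' @param alpha_level pruning significance level (step 5), 0.10.
#' @param prune run step 5 (default TRUE).
#' @param diagonal kernel diagonal convention, see [exp_kernel_weights()].
#' @return an `esfr_model`; the weights, basis and candidate set used are
#'   attached as attributes `weights`, `basis`, `candidates`.
#' @export
fit_esfr <- function(stations, weights = NULL, basis = NULL,
                     threshold = 0.10, alpha_level = 0.10, prune = TRUE,
                     diagonal = c("zero", "one")) {
  stopifnot(inherits(stations, "station_set"))
  if (is.null(weights)) weights <- spatial_weights(stations, match.arg(diagonal))
  if (is.null(basis)) basis <- eigen_basis(weights$C1)
  candidates <- select_candidates(basis, threshold)
  y <- stations$value
  X <- stations$covariates
  sel <- forward_stepwise_eigen(y, X, candidates, basis)
  model <- fit_ols(y, X, basis$vectors[, sel, drop = FALSE], sel)
  attr(model, "training") <- list(y = y, covariates = X,
                                  candidates = candidates, basis = basis)
  if (prune) model <- prune_and_refit(model, alpha_level)
  attr(model, "weights") <- weights
  attr(model, "basis") <- basis
  attr(model, "candidates") <- candidates
  model
}

#' Predict from a fitted model at new locations
#'
#' @param object an `esfr_model`.
#' @param newdata matrix/data frame with the model's covariate columns (raw
#'   scale).
#' @param eigen_values matrix of eigenvector values at the new locations,
#'   one column per entry of `object$eigen_indices` (raw eigenvector scale,
#'   e.g. from [nystrom_extend()]); required when the model has eigenvector
#'   terms.
#' @param ... unused.
#' @return numeric predictions on the raw response scale.
#' @export
predict.esfr_model <- function(object, newdata, eigen_values = NULL, ...) {
  X <- as.matrix(as.data.frame(newdata))[, object$covariate_names, drop = FALSE]
  m <- nrow(X)
  cols <- object$standardization$columns
  acc <- rep(object$intercept, m)
  for (nm in object$covariate_names) {
    s <- cols[[nm]]
    acc <- acc + object$beta[[nm]] * (X[, nm] - s[["mean"]]) / s[["sd"]]
  }
  if (length(object$eigen_indices)) {
    if (is.null(eigen_values))
      stop("model has eigenvector terms; supply eigen_values")
    Ev <- as.matrix(eigen_values)
    stopifnot(ncol(Ev) == length(object$eigen_indices))
    for (j in seq_along(object$eigen_indices)) {
      nm <- paste0("EV", object$eigen_indices[j])
      s <- cols[[nm]]
      acc <- acc + object$alpha[[nm]] * (Ev[, j] - s[["mean"]]) / s[["sd"]]
    }
  }
  r <- object$standardization$response
  r[["mean"]] + r[["sd"]] * acc
}

#' Percent change between two metric values
#'
#' The comparison arithmetic used in report tables: `increase` is
#' 100 (comparison - reference)/reference, `decrease` is
#' 100 (reference - comparison)/reference; both rounded half-up to one
#' decimal, matching the convention of printed model-comparison tables.
#'
#' @param reference baseline value (non-zero).
#' @param comparison value compared against the baseline.
#' @param mode `"increase"` or `"decrease"`.
#' @return percent, one decimal.
#' @export
percent_change <- function(reference, comparison, mode = c("increase", "decrease")) {
  mode <- match.arg(mode)
  if (reference == 0) stop("reference value must be non-zero")
  pc <- switch(mode,
               increase = 100 * (comparison - reference) / reference,
               decrease = 100 * (reference - comparison) / reference)
  round_half_up(pc, 1L)
}

#' Round half away from zero
#'
#' `round()` in R rounds half to even; printed report tables use the
#' familiar half-up convention, so it is implemented explicitly.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-12) / f
}

#' Serialize a fitted model to JSON
#'
#' Pruned covariates appear with `beta = null`, mirroring the "/" marker
#' convention of printed coefficient tables.
#'
#' @param model an `esfr_model`.
#' @param path optional file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
model_to_json <- function(model, path = NULL) {
  covs <- lapply(model$covariate_names, function(nm)
    list(name = nm, beta = unname(model$beta[[nm]]),
         p = unname(model$pvalues[[nm]])))
  covs <- c(covs, lapply(model$pruned, function(nm)
    list(name = nm, beta = NULL, p = NULL)))
  eig <- lapply(seq_along(model$eigen_indices), function(j)
    list(index = model$eigen_indices[j],
         alpha = unname(model$alpha[[paste0("EV", model$eigen_indices[j])]])))
  obj <- list(covariates = covs, eigen = eig, intercept = model$intercept,
              fit = model$fit[c("r2_adj", "rse", "mape", "aicc")],
              standardization = model$standardization)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
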