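#' Nystrom extension of eigenvectors to new locations
#'
#' Evaluates eigenvectors of the centered kernel at out-of-sample locations.
#' The kernel row from the new location to the training stations is
#' double-centered against the training kernel,
#' `ct_i = c_i - mean(c) - colmean_i(C0) + grandmean(C0)`, and projected:
#' `e_j(s0) = ct . e_j / lambda_j`. At a training station this reproduces
#' the stored eigenvector entry exactly, which is what makes in-sample
#' predictions of the mapped model agree with fitted values.
#'
#' @param basis an [eigen_basis()] built from `C0`'s centered form.
#' @param C0 the training kernel matrix (same diagonal convention the basis
#'   was built with).
#' @param kernel_row numeric vector of length n, `exp(-d(s0, s_i)/r)` with
#'   the training range `r`; or an m x n matrix for m locations.
#' @param indices eigenvector columns to extend (positive eigenvalues only).
#' @return m x length(indices) matrix of extended eigenvector values (a
#'   plain vector when a single location and single index).
#' @export
nystrom_extend <- function(basis, C0, kernel_row, indices) {
  stopifnot(inherits(basis, "eigen_basis"))
  C0 <- as.matrix(C0)
  n <- basis$n
  lam <- basis$values[indices]
  if (any(lam <= 0))
    stop("Nystrom extension undefined for non-positive eigenvalues: index ",
         paste(indices[lam <= 0], collapse = ", "))
  K <- if (is.matrix(kernel_row)) kernel_row else matrix(kernel_row, nrow = 1L)
  stopifnot(ncol(K) == n)
  ct <- K - rowMeans(K) -
    matrix(colMeans(C0), nrow(K), n, byrow = TRUE) + mean(C0)
  out <- (ct %*% basis$vectors[, indices, drop = FALSE]) %*%
    diag(1 / lam, nrow = length(indices))
  colnames(out) <- paste0("EV", indices)
  if (nrow(out) == 1L && length(indices) == 1L) return(as.numeric(out))
  out
}

#' Leave-one-out cross-validation
#'
#' For each station: rebuild the spatial weights from scratch on the n - 1
#' training stations (distances, MST range, kernel, centering), re-run
#' eigendecomposition, candidate screening, stepwise selection and the OLS
#' fit, extend the selected eigenvectors to the held-out location with
#' [nystrom_extend()], and predict. The non-spatial (`"gmlr"`) variant skips
#' every eigenvector step. Folds with rank-deficient designs are flagged
#' and excluded from the error summary.
#'
#' @param stations a [station_set()] (n >= 10).
#' @param method `"esfr"` or `"gmlr"`.
#' @param threshold,alpha_level,prune,diagonal as in [fit_esfr()].
#' @param max_candidates optional cap on the candidate pool per fold (by
#'   descending eigenvalue); default all.
#' @return object of class `cv_result`: `per_station` (data frame
#'   station_id, observed, predicted, failed), `mse`, `rmse`, `n_folds`,
#'   `n_failed`, `method`.
#' @export
loocv <- function(stations, method = c("esfr", "gmlr"), threshold = 0.10,
                  alpha_level = 0.10, prune = TRUE,
                  diagonal = c("zero", "one"), max_candidates = Inf) {
  method <- match.arg(method)
  diagonal <- match.arg(diagonal)
  stopifnot(inherits(stations, "station_set"))
  n <- n_stations(stations)
  if (n < 10L) stop("LOOCV needs at least 10 stations")
  D_full <- pairwise_distances(stations)
  pred <- rep(NA_real_, n)
  failed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    y <- stations$value[tr]
    X <- stations$covariates[tr, , drop = FALSE]
    res <- tryCatch({
      if (method == "esfr") {
        D <- D_full[tr, tr]
        r <- mst_longest_edge(D)
        C0 <- exp_kernel_weights(D, r, diagonal)
        basis <- eigen_basis(center_weights(C0))
        cand <- select_candidates(basis, threshold)
        if (is.finite(max_candidates) && length(cand$indices) > max_candidates)
          cand$indices <- cand$indices[seq_len(max_candidates)]
        sel <- forward_stepwise_eigen(y, X, cand, basis)
        model <- fit_ols(y, X, basis$vectors[, sel, drop = FALSE], sel)
        attr(model, "training") <- list(y = y, covariates = X,
                                        candidates = cand, basis = basis)
        if (prune) model <- prune_and_refit(model, alpha_level)
        ev <- NULL
        if (length(model$eigen_indices)) {
          krow <- exp(-D_full[i, tr] / r)
          ev <- nystrom_extend(basis, C0, krow, model$eigen_indices)
          ev <- matrix(ev, nrow = 1L)
        }
        predict(model, stations$covariates[i, , drop = FALSE], ev)
      } else {
        model <- fit_gmlr(y, X)
        attr(model, "training") <- list(y = y, covariates = X,
                                        candidates = NULL, basis = NULL)
        if (prune) model <- prune_and_refit(model, alpha_level)
        predict(model, stations$covariates[i, , drop = FALSE])
      }
    }, error = function(e) e)
    if (inherits(res, "error")) failed[i] <- TRUE else pred[i] <- res
  }
  ok <- !failed
  err <- stations$value[ok] - pred[ok]
  mse <- mean(err^2)
  structure(list(per_station = data.frame(station_id = stations$station_id,
                                          observed = stations$value,
                                          predicted = pred, failed = failed),
                 mse = mse, rmse = sqrt(mse), n_folds = n,
                 n_failed = sum(failed), method = method),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOOCV (%s): %d folds (%d failed), MSE = %.4g, RMSE = %.4g\n",
              x$method, x$n_folds, x$n_failed, x$mse, x$rmse))
  invisible(x)
}

#' Persist a cross-validation result
#'
#' Per-station table as CSV plus a JSON summary.
#'
#' @param cv a `cv_result`.
#' @param stem path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return the stem, invisibly.
#' @export
write_cv_result <- function(cv, stem) {
  utils::write.csv(cv$per_station, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(mse = cv$mse, rmse = cv$rmse,
                            n_folds = cv$n_folds, n_failed = cv$n_failed,
                            method = cv$method),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
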