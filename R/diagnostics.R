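#' Global Moran's I with significance
#'
#' I = (n/S0) sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2.
#' Inference uses the analytic normal approximation under the randomization
#' assumption by default (expectation -1/(n-1), closed-form variance), with
#' a one-sided upper-tail p-value for the alternative of positive spatial
#' autocorrelation; negative I therefore yields p near 1. A permutation
#' test is available behind `method = "permutation"`.
#'
#' @param values numeric vector, non-constant.
#' @param W spatial weights: a matrix (zero diagonal) or a
#'   [spatial_weights()] object (its `C0` is used).
#' @param method `"normal"` (randomization variance) or `"permutation"`.
#' @param nperm permutations when `method = "permutation"`.
#' @param row_standardize divide each row of the weights by its sum first.
#' @return object of class `moran_result`: `I`, `expected`, `variance`, `z`,
#'   `p`, `n`, `S0`, `method`.
#' @export
global_moran <- function(values, W, method = c("normal", "permutation"),
                         nperm = 999L, row_standardize = FALSE) {
  method <- match.arg(method)
  x <- as.numeric(values)
  if (stats::sd(x) == 0) stop("values are constant: Moran's I undefined")
  W <- if (inherits(W, "spatial_weights")) W$C0 else as.matrix(W)
  n <- length(x)
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (row_standardize) {
    rs <- rowSums(W)
    W <- W / ifelse(rs == 0, 1, rs)
  }
  z <- x - mean(x)
  S0 <- sum(W)
  I <- (n / S0) * as.numeric(crossprod(z, W %*% z)) / sum(z * z)
  EI <- -1 / (n - 1)
  if (method == "normal") {
    S1 <- 0.5 * sum((W + t(W))^2)
    S2 <- sum((rowSums(W) + colSums(W))^2)
    b2 <- n * sum(z^4) / (sum(z^2))^2
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    zs <- (I - EI) / sqrt(VI)
    p <- stats::pnorm(zs, lower.tail = FALSE)
  } else {
    perm <- vapply(seq_len(nperm), function(k) {
      zp <- z[sample.int(n)]
      (n / S0) * as.numeric(crossprod(zp, W %*% zp)) / sum(zp * zp)
    }, numeric(1))
    VI <- stats::var(perm)
    zs <- (I - mean(perm)) / sqrt(VI)
    p <- (1 + sum(perm >= I)) / (1 + nperm)
  }
  structure(list(I = I, expected = EI, variance = VI, z = zs, p = p,
                 n = n, S0 = S0, method = method),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, z = %.3f, one-sided p = %.4g, %s)\n",
              x$I, x$expected, x$z, x$p, x$method))
  invisible(x)
}

#' Moran's I of model residuals
#'
#' The filtering check: a well-specified spatially filtered model should
#' leave residuals with an insignificant Moran's I, while the non-spatial
#' baseline on spatially structured data should not.
#'
#' @param model an `esfr_model`.
#' @param W weights as in [global_moran()].
#' @param ... passed to [global_moran()].
#' @return a `moran_result`.
#' @export
residual_moran <- function(model, W, ...) {
  stopifnot(inherits(model, "esfr_model"))
  global_moran(model$residuals, W, ...)
}

#' Pearson correlation screening table
#'
#' Correlation of the exposure value with each covariate, with two-tailed
#' t-based p-values and the printed-table significance markers: "*" at the
#' 0.05 level, "**" at 0.01. Zero-variance covariates are flagged
#' undefined rather than erroring.
#'
#' @param stations a [station_set()] with covariates.
#' @param levels two significance levels, default `c(0.05, 0.01)`.
#' @return data frame with columns `covariate`, `pcc`, `p`, `marker`.
#' @export
pearson_table <- function(stations, levels = c(0.05, 0.01)) {
  stopifnot(inherits(stations, "station_set"))
  y <- stations$value
  X <- stations$covariates
  out <- lapply(colnames(X), function(nm) {
    xv <- X[, nm]
    if (stats::sd(xv) == 0 || stats::sd(y) == 0)
      return(data.frame(covariate = nm, pcc = NA_real_, p = NA_real_,
                        marker = "undefined"))
    ct <- stats::cor.test(y, xv, method = "pearson", alternative = "two.sided")
    mk <- if (ct$p.value <= min(levels)) "**"
          else if (ct$p.value <= max(levels)) "*" else ""
    data.frame(covariate = nm, pcc = unname(ct$estimate),
               p = ct$p.value, marker = mk)
  })
  do.call(rbind, out)
}
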