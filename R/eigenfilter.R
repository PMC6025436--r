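#' Spectral decomposition of the centered weights matrix
#'
#' Full real symmetric eigendecomposition of C1. Eigenvalues are sorted in
#' descending order; each eigenvector is unit length with its
#' largest-magnitude entry made positive (ties broken by the first such
#' entry) so that coefficients and filter maps are reproducible across
#' LAPACK builds.
#'
#' @param C1 symmetric matrix, typically from [center_weights()].
#' @param tol symmetry tolerance (absolute), scaled by n internally.
#' @return object of class `eigen_basis` with fields `values` (descending),
#'   `vectors` (orthonormal columns), `n` and `source_hash`.
#' @export
eigen_basis <- function(C1, tol = 1e-9) {
  C1 <- as.matrix(C1)
  n <- nrow(C1)
  if (n != ncol(C1)) stop("C1 must be square")
  if (max(abs(C1 - t(C1))) > tol * n)
    stop("C1 is not symmetric within tolerance")
  es <- eigen((C1 + t(C1)) / 2, symmetric = TRUE)
  E <- es$vectors
  for (j in seq_len(n)) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  structure(list(values = es$values, vectors = E, n = n,
                 source_hash = .matrix_fingerprint(C1)),
            class = "eigen_basis")
}

# cheap deterministic fingerprint; enough to detect basis/weights mismatch
.matrix_fingerprint <- function(M) {
  s <- c(nrow(M), sum(M), sum(M * M), sum(abs(M)))
  paste(formatC(s, digits = 12, format = "g"), collapse = ":")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("eigen_basis: n = %d, lambda_1 = %.4g, lambda_n = %.4g\n",
              x$n, x$values[1L], x$values[x$n]))
  invisible(x)
}

#' Candidate eigenvector selection by eigenvalue ratio
#'
#' Keeps the eigenvectors whose eigenvalue is at least `threshold` times the
#' leading eigenvalue (boundary inclusive). These are the patterns with the
#' strongest positive spatial autocorrelation; the default ratio of 0.10 is
#' the conventional screening rule for positively autocorrelated responses.
#'
#' @param basis an [eigen_basis()].
#' @param threshold ratio in (0, 1]; default 0.10.
#' @return object of class `candidate_set`: `indices` (descending-lambda
#'   order) and `threshold`.
#' @export
select_candidates <- function(basis, threshold = 0.10) {
  stopifnot(inherits(basis, "eigen_basis"))
  l1 <- basis$values[1L]
  if (l1 <= 0)
    stop("no positive-autocorrelation eigenvectors: leading eigenvalue <= 0")
  idx <- which(basis$values / l1 >= threshold)
  structure(list(indices = idx, threshold = threshold),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d eigenvectors at lambda ratio >= %g\n",
              length(x$indices), x$threshold))
  invisible(x)
}

#' Moran coefficient of a vector under kernel weights
#'
#' MC(v) = (n / S0) * (v' C1 v) / (v' M v) with S0 the total weight and M
#' the centering projector. For an eigenvector of C1 this reduces exactly to
#' (n / S0) * lambda, the identity that makes the eigenvalue ordering a
#' spatial-autocorrelation ordering.
#'
#' @param v numeric vector, non-constant.
#' @param C0 raw (uncentered) weights matrix.
#' @return scalar Moran coefficient.
#' @export
moran_coefficient <- function(v, C0) {
  v <- as.numeric(v)
  if (stats::sd(v) == 0) stop("v is constant: Moran coefficient undefined")
  C0 <- as.matrix(C0)
  n <- length(v)
  stopifnot(nrow(C0) == n)
  z <- v - mean(v)
  C1 <- center_weights(C0)
  (n / sum(C0)) * as.numeric(crossprod(v, C1 %*% v)) / sum(z * z)
}
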