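#' Pairwise Euclidean distances between stations
#'
#' @param stations a [station_set()], or a two-column matrix/data frame of
#'   planar coordinates.
#' @return symmetric n x n distance matrix with zero diagonal and strictly
#'   positive off-diagonal entries.
#' @export
pairwise_distances <- function(stations) {
  if (inherits(stations, "station_set")) {
    xy <- cbind(stations$x, stations$y)
    ids <- stations$station_id
  } else {
    xy <- as.matrix(stations)[, 1:2, drop = FALSE]
    ids <- as.character(seq_len(nrow(xy)))
  }
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- NULL
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    idx <- which(D == 0 & upper.tri(D), arr.ind = TRUE)[1L, ]
    stop(sprintf("stations %s and %s are coincident (distance 0)",
                 ids[idx[1L]], ids[idx[2L]]))
  }
  D
}

#' Longest edge of the minimum spanning tree
#'
#' The kernel range `r` of the exponential distance-decay weights is the
#' maximum edge weight of a minimum spanning tree over the complete graph of
#' stations: the smallest distance at which the network is still connected.
#' Computed with Prim's algorithm on the dense distance matrix.
#'
#' @param D symmetric distance matrix, n >= 2.
#' @return scalar `r`, the longest MST edge.
#' @export
mst_longest_edge <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 stations for a spanning tree")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  in_tree <- rep(FALSE, n)
  in_tree[1L] <- TRUE
  best <- D[1L, ]            # cheapest connection of each node to the tree
  best[1L] <- Inf
  longest <- 0
  for (step in seq_len(n - 1L)) {
    j <- which.min(ifelse(in_tree, Inf, best))
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  longest
}

#' Exponential distance-decay kernel weights
#'
#' Off-diagonal entries are `exp(-d_ij / r)`; the diagonal is forced to zero
#' by default (self-influence excluded, the usual Moran-operator convention).
#' Both conventions only shift the centered spectrum by a constant pattern;
#' the flag exists because either choice is defensible.
#'
#' @param D symmetric distance matrix.
#' @param r kernel range (> 0), typically from [mst_longest_edge()].
#' @param diagonal `"zero"` (default) or `"one"` (keep exp(0) = 1).
#' @return symmetric nonnegative weights matrix `C0`.
#' @export
exp_kernel_weights <- function(D, r, diagonal = c("zero", "one")) {
  diagonal <- match.arg(diagonal)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("kernel range r must be a positive scalar")
  C0 <- exp(-as.matrix(D) / r)
  if (diagonal == "zero") diag(C0) <- 0
  C0
}

#' Double-center a weights matrix
#'
#' Applies the centering projector M = I - 11'/n on both sides:
#' C1 = M C0 M. Every row and column of C1 sums to zero, so the constant
#' vector is in its null space and the remaining eigenvectors are the
#' candidate spatial patterns.
#'
#' @param C0 square symmetric matrix.
#' @return centered matrix `C1` (symmetric, zero row/column sums).
#' @export
center_weights <- function(C0) {
  C0 <- as.matrix(C0)
  if (nrow(C0) != ncol(C0)) stop("C0 must be square")
  rm_ <- rowMeans(C0)
  cm_ <- colMeans(C0)
  g <- mean(C0)
  C1 <- C0 - outer(rm_, rep(1, ncol(C0))) - outer(rep(1, nrow(C0)), cm_) + g
  (C1 + t(C1)) / 2  # symmetrize away rounding asymmetry
}

#' Build the spatial weights object for a station network
#'
#' Convenience constructor running the distance / MST-range / kernel /
#' centering chain and bundling the results.
#'
#' @param stations a [station_set()] (or coordinate matrix).
#' @param diagonal diagonal convention for [exp_kernel_weights()].
#' @return object of class `spatial_weights` with fields `C0`, `r`, `C1`,
#'   `D`, `diagonal` and `n`.
#' @export
spatial_weights <- function(stations, diagonal = c("zero", "one")) {
  diagonal <- match.arg(diagonal)
  D <- pairwise_distances(stations)
  r <- mst_longest_edge(D)
  C0 <- exp_kernel_weights(D, r, diagonal)
  C1 <- center_weights(C0)
  tol <- 1e-9 * nrow(C0)
  stopifnot(max(abs(rowSums(C1))) < tol, max(abs(colSums(C1))) < tol)
  structure(list(C0 = C0, r = r, C1 = C1, D = D, diagonal = diagonal,
                 n = nrow(C0)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: n = %d, r = %.4g, diagonal = %s\n",
              x$n, x$r, x$diagonal))
  invisible(x)
}

#' Persist / restore spatial weights
#'
#' Dense matrix as a TSV alongside a JSON sidecar recording `n`, `r` and the
#' diagonal convention, so a run can be reproduced without the input table.
#'
#' @param w a `spatial_weights` object.
#' @param stem path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return the stem, invisibly.
#' @export
write_weights <- function(w, stem) {
  utils::write.table(w$C0, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n = w$n, r = w$r, diagonal_convention = w$diagonal),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_weights
#' @export
read_weights <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  C0 <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t"))
  dimnames(C0) <- NULL
  structure(list(C0 = C0, r = meta$r, C1 = center_weights(C0), D = NULL,
                 diagonal = meta$diagonal_convention, n = meta$n),
            class = "spatial_weights")
}
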