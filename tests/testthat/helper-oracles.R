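# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# exhaustive minimum-spanning-tree oracle: enumerate all labelled trees on n
# nodes via Prufer sequences (n^(n-2) of them), score each, return the max
# edge of the cheapest tree. Feasible up to n = 7 (16807 trees).
prufer_decode <- function(seq_, n) {
  deg <- tabulate(seq_, n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq_)) {
    leaf <- which(deg == 1L)[1L]
    edges[i, ] <- c(leaf, seq_[i])
    deg[leaf] <- 0L
    deg[seq_[i]] <- deg[seq_[i]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

exhaustive_mst_max_edge <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 3L, n <= 7L)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best_total <- Inf
  best_max <- NA_real_
  for (k in seq_len(nrow(seqs))) {
    ed <- prufer_decode(seqs[k, ], n)
    w <- D[cbind(ed[, 1], ed[, 2])]
    tot <- sum(w)
    if (tot < best_total) {
      best_total <- tot
      best_max <- max(w)
    }
  }
  best_max
}

# brute-force double-sum Moran's I
brute_moran_i <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# randomization variance of Moran's I, coded directly from the closed form
brute_moran_var <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  S0 <- sum(W)
  S1 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    S1 <- S1 + (W[i, j] + W[j, i])^2
  S1 <- S1 / 2
  S2 <- 0
  for (i in seq_len(n))
    S2 <- S2 + (sum(W[i, ]) + sum(W[, i]))^2
  b2 <- n * sum(z^4) / sum(z^2)^2
  EI <- -1 / (n - 1)
  (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
      b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
}

# small random station fixture with independent covariates
rand_stations <- function(n, seed, p = 3L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  station_set(sprintf("st%02d", seq_len(n)),
              runif(n, 0, 100), runif(n, 0, 100),
              rnorm(n, 50, 8), X)
}

# fast default scene for tests that just need filter-bearing data
quick_scene <- function(seed, n = 60L, region = c(0, 200, 0, 150), ...) {
  simulate_scene(sim_config(seed = seed, n_stations = n, region = region, ...),
                 rasters = FALSE)
}
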