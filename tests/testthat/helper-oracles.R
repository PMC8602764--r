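# Independent oracles used to cross-check the package's own implementations.
# These deliberately use the slowest, most literal formulation of each
# definition so they share no code path with the functions under test.

# Coordinate-descent lasso: minimize (w/2) ||x - A c||^2 + ||c||_1.
cd_lasso <- function(A, x, w, max_sweeps = 5000, tol = 1e-12) {
  m <- ncol(A)
  c_vec <- numeric(m)
  r <- x
  a2 <- colSums(A^2)
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(m)) {
      if (a2[j] == 0) next
      old <- c_vec[j]
      rho_j <- w * sum(A[, j] * (r + A[, j] * old))
      new <- sign(rho_j) * max(abs(rho_j) - 1, 0) / (w * a2[j])
      if (new != old) {
        r <- r - A[, j] * (new - old)
        delta <- max(delta, abs(new - old))
        c_vec[j] <- new
      }
    }
    if (delta < tol) break
  }
  c_vec
}

# Full self-representation by per-column coordinate descent with the
# diagonal excluded; returns the n x n coefficient matrix.
cd_ssr <- function(X, w) {
  n <- ncol(X)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A <- X[, -i, drop = FALSE]
    C[-i, i] <- cd_lasso(A, X[, i], w)
  }
  C
}

# Brute-force variance-split scan: literal evaluation of every admissible
# cut with stats::var on both segments.
brute_split <- function(scores, decreasing = TRUE) {
  p <- length(scores)
  s <- sort(scores, decreasing = decreasing)
  best_size <- NA
  best_obj <- Inf
  for (m in seq_len(p - 1)) {
    if (!(m > 0.1 * p && m < 0.5 * p)) next
    v1 <- if (m < 2) 0 else stats::var(s[seq_len(m)])
    v2 <- if (p - m < 2) 0 else stats::var(s[(m + 1):p])
    if (v1 + v2 < best_obj) {
      best_obj <- v1 + v2
      best_size <- m
    }
  }
  best_size
}

# Literal triple loop over (i, j, z) for the weighted common-neighbor score.
brute_adamic_adar <- function(S, mask) {
  n <- nrow(S)
  A <- S > 0
  deg <- rowSums(A)
  I <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (mask[i, j] != 1 || i == j) next
    acc <- 0
    for (z in seq_len(n)) {
      if (z != i && z != j && A[i, z] && A[j, z]) {
        acc <- acc + (S[i, z] + S[j, z]) / deg[z]
      }
    }
    I[i, j] <- acc
  }
  I
}

# Random symmetric nonnegative similarity with zero diagonal and given
# edge density.
random_sparse_sim <- function(n, density = 0.2) {
  S <- matrix(0, n, n)
  up <- upper.tri(S)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) > density] <- 0
  S[up] <- vals
  S <- S + t(S)
  S
}

# Block-diagonal similarity with given block sizes and positive
# within-block weights.
block_sim <- function(sizes, weight = 1, noise = 0) {
  n <- sum(sizes)
  S <- matrix(0, n, n)
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b] + sizes[b] - 1)
    S[idx, idx] <- weight
  }
  if (noise > 0) {
    up <- upper.tri(S)
    flip <- up & matrix(stats::runif(n * n) < noise, n, n)
    S[flip] <- S[flip] + 0.1
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
  }
  diag(S) <- 0
  S
}

# Connected-component count via igraph, independent of the spectral code.
igraph_components_oracle <- function(S) {
  g <- igraph::graph_from_adjacency_matrix(S > 0, mode = "undirected")
  igraph::components(g)$no
}

# Unit-norm columns realizing a given positive-definite Gram matrix.
cells_from_gram <- function(G) {
  X <- chol(G)
  sweep(X, 2, sqrt(colSums(X^2)), "/")
}
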