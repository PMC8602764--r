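normalized_laplacian <- function(S) {
  stopifnot(isSymmetric(unname(S), tol = 1e-8))
  d <- rowSums(S)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  n <- nrow(S)
  L <- diag(n) - S * (inv_sqrt %o% inv_sqrt)
  (L + t(L)) / 2
}

#' Spectral clustering on a similarity matrix
#'
#' Embeds cells with the bottom K eigenvectors of the symmetric normalized
#' Laplacian `L = I - D^{-1/2} S D^{-1/2}`, row-normalizes the embedding, and
#' partitions it with seeded k-means (50 restarts). Isolated cells (zero
#' degree) are embedded at the origin and are assigned to the largest cluster
#' with a warning, since the graph carries no information about them.
#'
#' @param S Symmetric nonnegative similarity matrix.
#' @param K Number of clusters, `2 <= K <= n - 1`.
#' @param seed Integer seed controlling the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return A list of class `cluster_result`: `labels` (integers 1..K), `K`,
#'   `eigenvalues` (ascending Laplacian spectrum head), `seed`.
#' @export
spectral_cluster <- function(S, K, seed = 1, nstart = 50) {
  n <- nrow(S)
  if (K < 2 || K > n - 1) stop("K must be in [2, n-1], got ", K)
  L <- normalized_laplacian(S)
  eig <- eigen(L, symmetric = TRUE)
  ev <- rev(eig$values)                         # ascending
  U <- eig$vectors[, n:(n - K + 1), drop = FALSE]  # bottom K eigenvectors
  rn <- sqrt(rowSums(U^2))
  isolated <- rowSums(S) == 0
  rn[rn == 0] <- 1
  U <- U / rn
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  km <- stats::kmeans(U, centers = K, nstart = nstart, iter.max = 100)
  labels <- km$cluster
  if (any(isolated)) {
    warning(sum(isolated), " isolated cell(s) assigned to the largest cluster")
    labels[isolated] <- as.integer(names(which.max(table(labels[!isolated]))))
  }
  structure(list(labels = as.integer(labels), K = K,
                 eigenvalues = ev[seq_len(min(n, K + 10))], seed = seed),
            class = "cluster_result")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Spectral clustering into K =", x$K, "groups\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Estimate the number of clusters by the eigengap heuristic
#'
#' Computes the ascending eigenvalues of the symmetric normalized Laplacian
#' and returns the index i (searched from 2 to `k_max`) with the largest gap
#' `lambda[i+1] - lambda[i]`. On an exactly block-diagonal similarity this is
#' the number of connected components (the multiplicity of the zero
#' eigenvalue). K = 1 is never returned: a single cluster is not a useful
#' answer for cell typing.
#'
#' @param S Symmetric nonnegative similarity matrix.
#' @param k_max Largest K considered; default `min(n - 1, 30)`.
#' @return Integer estimate of the number of clusters.
#' @export
estimate_k_eigengap <- function(S, k_max = NULL) {
  n <- nrow(S)
  if (is.null(k_max)) k_max <- min(n - 1, 30)
  stopifnot(k_max >= 2, k_max <= n - 1)
  L <- normalized_laplacian(S)
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  idx <- 2:k_max
  gaps <- ev[idx + 1] - ev[idx]
  as.integer(idx[which.max(gaps)])
}

contingency <- function(l1, l2) {
  if (length(l1) != length(l2)) stop("label vectors must have equal length")
  table(factor(l1), factor(l2))
}

#' Normalized mutual information between two labelings
#'
#' `NMI = I(L1, L2) / ((H(L1) + H(L2)) / 2)` with natural-log entropies;
#' defined as 0 when both partitions are trivial (zero entropy). Symmetric
#' and invariant to label renaming.
#'
#' @param l1,l2 Integer label vectors of equal length.
#' @return Value in \[0, 1\].
#' @export
nmi <- function(l1, l2) {
  tab <- contingency(l1, l2)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij)
  pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  h1 <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  h2 <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (h1 + h2 == 0) return(0)
  mi / ((h1 + h2) / 2)
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement corrected for chance from the contingency table:
#' 1 for identical partitions, approximately 0 under independence, possibly
#' negative. Symmetric and invariant to label renaming.
#'
#' @param l1,l2 Integer label vectors of equal length.
#' @return ARI value (at most 1).
#' @export
ari <- function(l1, l2) {
  tab <- contingency(l1, l2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / denom
}
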