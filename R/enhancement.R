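#' Neighborhood size for similarity enhancement
#'
#' k = round(0.1 * n) for datasets with fewer than 5000 cells, 100 otherwise,
#' never below 1.
#'
#' @param n Number of cells.
#' @return Integer k.
#' @export
choose_k <- function(n) {
  stopifnot(n >= 2)
  k <- if (n < 5000) round(0.1 * n) else 100L
  max(1L, as.integer(k))
}

#' K-nearest-neighbor indicator matrix
#'
#' `P[i, j] = 1` iff cell j is among the k largest raw similarities in row i
#' of `S`, self excluded. Ties at the k-th rank are broken toward the smaller
#' column index, so the indicator is deterministic.
#'
#' @param S Similarity matrix (raw values; negatives allowed for ranking).
#' @param k Neighborhood size, `1 <= k <= n - 1`.
#' @return Binary n-by-n matrix with zero diagonal and k ones per row.
#' @export
knn_indicator <- function(S, k) {
  n <- nrow(S)
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1], got ", k)
  P <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    v <- S[i, ]
    v[i] <- -Inf
    P[i, order(v, decreasing = TRUE)[seq_len(k)]] <- 1L
  }
  P
}

#' Mark zero similarities supported by pairwise-similarity neighborhoods
#'
#' An entry (i, j) of the sparse affinity is marked missing (a candidate for
#' imputation) when it is zero but j is a k-nearest neighbor of i under at
#' least one of the classical pairwise similarities.
#'
#' @param sim_sparse Sparse subspace similarity (nonnegative, zero diagonal).
#' @param indicators List of binary KNN indicator matrices from
#'   [knn_indicator()], all with the same k.
#' @return Binary n-by-n mask, zero diagonal.
#' @export
mark_missing <- function(sim_sparse, indicators) {
  stopifnot(length(indicators) >= 1)
  anyP <- Reduce(`pmax`, indicators)
  mask <- (sim_sparse == 0) * (anyP == 1)
  diag(mask) <- 0
  storage.mode(mask) <- "integer"
  mask
}

#' Impute marked similarities by weighted common neighbors
#'
#' For each marked pair (i, j), sums over common neighbors z of i and j on
#' the nonzero pattern of `sim_sparse`:
#' \deqn{I[i, j] = \sum_{z \in CN(i,j)} \frac{S[i,z] + S[j,z]}{|\Gamma(z)|},}
#' a weighted Adamic/Adar score in which each shared neighbor contributes its
#' similarity to both endpoints, discounted by its degree. Pairs with no
#' common neighbor stay 0. Every score reads the original `sim_sparse`; there
#' is no sequential filling-in, so the result is order-independent.
#'
#' @param sim_sparse Nonnegative symmetric similarity, zero diagonal.
#' @param mask Binary matrix from [mark_missing()].
#' @return Matrix of imputed values, nonzero only where `mask == 1`.
#' @export
adamic_adar_impute <- function(sim_sparse, mask) {
  stopifnot(all(sim_sparse >= 0))
  A <- (sim_sparse > 0) * 1
  deg <- rowSums(A)
  B <- A / ifelse(deg > 0, deg, 1)      # B[z, j] = A[z, j] / |Gamma(z)|
  M <- sim_sparse %*% B                 # sum_z S[i,z] A[z,j] / deg(z)
  I <- (M + t(M)) * (mask == 1)
  diag(I) <- 0
  I
}

#' Assemble the enhanced similarity matrix
#'
#' `E = I + t(I) + sim_sparse`: the imputed common-neighbor scores are
#' symmetrized and added on top of the sparse affinity, so enhancement never
#' removes similarity.
#'
#' @param sim_sparse Nonnegative symmetric similarity, zero diagonal.
#' @param I_sim Imputed matrix from [adamic_adar_impute()].
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
assemble_enhanced <- function(sim_sparse, I_sim) {
  stopifnot(all(sim_sparse >= 0), all(I_sim >= 0))
  E <- I_sim + t(I_sim) + sim_sparse
  diag(E) <- 0
  E
}

#' One-call similarity enhancement
#'
#' Runs [choose_k()], [knn_indicator()] on each classical similarity,
#' [mark_missing()], [adamic_adar_impute()], and [assemble_enhanced()].
#'
#' @param sim_sparse Sparse subspace similarity.
#' @param pairwise_sims Named list of classical similarity matrices used for
#'   neighbor ranking.
#' @param k Neighborhood size; chosen by [choose_k()] when `NULL`.
#' @return List with `E`, `I_sim`, `mask`, `k`, and `n_imputed` (count of
#'   marked entries that received a positive score).
#' @export
enhance_similarity <- function(sim_sparse, pairwise_sims, k = NULL) {
  n <- nrow(sim_sparse)
  if (is.null(k)) k <- choose_k(n)
  indicators <- lapply(pairwise_sims, knn_indicator, k = k)
  mask <- mark_missing(sim_sparse, indicators)
  I_sim <- adamic_adar_impute(sim_sparse, mask)
  E <- assemble_enhanced(sim_sparse, I_sim)
  list(E = E, I_sim = I_sim, mask = mask, k = k, n_imputed = sum(I_sim > 0))
}
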