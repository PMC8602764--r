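#' Classical pairwise cell-cell similarities
#'
#' Pearson correlation, Spearman correlation (average ranks for ties), and
#' cosine similarity between cells (columns), computed across genes. Cells
#' that are constant across genes get correlation 0 with everything by
#' convention (a constant profile carries no information); the diagonal is
#' always 1.
#'
#' @param X Genes-by-cells matrix.
#' @return Symmetric n-by-n similarity matrix with unit diagonal.
#' @name pairwise_similarity
NULL

cor_similarity <- function(X, method) {
  S <- suppressWarnings(stats::cor(X, method = method))
  S[is.na(S)] <- 0   # constant columns: zero by convention
  diag(S) <- 1
  (S + t(S)) / 2
}

#' @rdname pairwise_similarity
#' @export
pearson_similarity <- function(X) cor_similarity(X, "pearson")

#' @rdname pairwise_similarity
#' @export
spearman_similarity <- function(X) cor_similarity(X, "spearman")

#' @rdname pairwise_similarity
#' @export
cosine_similarity <- function(X) {
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) stop("zero column: cosine similarity undefined for cell ",
                          which(nrm == 0)[1])
  S <- crossprod(sweep(X, 2, nrm, "/"))
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Clip negative similarities to zero
#'
#' Graph constructions (Laplacian score weights, common-neighbor imputation)
#' require nonnegative edge weights; negative correlations are clipped to 0.
#' Neighbor ranking elsewhere uses raw values.
#'
#' @param S Similarity matrix.
#' @return `S` with negative entries set to 0.
#' @export
clip_nonnegative <- function(S) {
  S[S < 0] <- 0
  S
}
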