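#' Laplacian score of each gene on a cell-similarity graph
#'
#' Measures how each gene's expression profile varies along a weighted
#' cell-cell graph. With degree matrix `D = diag(rowSums(S))`, Laplacian
#' `L = D - S`, and the gene profile centered against the degree-weighted
#' mean, the score of gene r is
#' \deqn{LS_r = \frac{\tilde f_r^\top L \tilde f_r}{\tilde f_r^\top D \tilde f_r}.}
#' Genes that are constant (after centering) score 0 by convention. Scores
#' are invariant to shifting or rescaling a gene.
#'
#' @param X Genes-by-cells matrix.
#' @param S Symmetric nonnegative similarity matrix (clip correlations with
#'   [clip_nonnegative()] first).
#' @return Numeric vector of length `nrow(X)`, named by gene.
#' @export
laplacian_score <- function(X, S) {
  if (any(S < 0)) stop("similarity must be nonnegative; clip first")
  d <- rowSums(S)
  if (all(d == 0)) stop("degenerate graph: all similarities are zero")
  Dsum <- sum(d)
  # center each gene against the degree-weighted mean
  F0 <- X - (X %*% d / Dsum)[, rep(1, ncol(X)), drop = FALSE]
  den <- drop(F0^2 %*% d)
  num <- den - rowSums(F0 * (F0 %*% S))   # f' L f = f' D f - f' S f
  score <- ifelse(den <= .Machine$double.eps * Dsum, 0, num / den)
  names(score) <- rownames(X)
  score
}

#' Split genes by the adaptive variance threshold
#'
#' Sorts Laplacian scores in decreasing order and scans every admissible cut
#' position, choosing the split into a high-score set G1 and its complement
#' G2 that minimizes `var(scores in G1) + var(scores in G2)` subject to
#' `0.1 * p < |G1| < 0.5 * p` (strict). Ties are broken toward the smaller
#' G1. The scan is exact: every admissible size is evaluated using
#' prefix-sum variance updates.
#'
#' @param scores Numeric vector of p gene scores (p >= 20 so the window is
#'   non-trivial).
#' @param decreasing Rank direction; the default keeps high scores in G1.
#' @return A list of class `gene_split` with `g1` (indices into `scores` of
#'   the selected set), `g2`, `size` (= |G1|), `objective`, and `order` (the
#'   ranking permutation).
#' @export
split_threshold <- function(scores, decreasing = TRUE) {
  p <- length(scores)
  if (p < 20) stop("need at least 20 genes for the threshold window")
  ord <- order(scores, decreasing = decreasing)
  s <- scores[ord]
  sizes <- seq_len(p - 1)
  sizes <- sizes[sizes > 0.1 * p & sizes < 0.5 * p]
  if (!length(sizes)) stop("threshold window empty for p = ", p)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  tot <- cs[p]
  tot2 <- cs2[p]
  segvar <- function(sum1, sum2, m) ifelse(m < 2, 0, (sum2 - sum1^2 / m) / (m - 1))
  obj <- segvar(cs[sizes], cs2[sizes], sizes) +
    segvar(tot - cs[sizes], tot2 - cs2[sizes], p - sizes)
  best <- sizes[which.min(obj)]        # which.min takes the first tie = smaller |G1|
  structure(list(g1 = sort(ord[seq_len(best)]), g2 = sort(ord[-seq_len(best)]),
                 size = best, objective = min(obj), order = ord),
            class = "gene_split")
}

#' Select informative genes by intersecting four similarity views
#'
#' Scores every gene by the Laplacian score under each supplied similarity
#' graph (typically the sparse subspace affinity plus Pearson, Spearman, and
#' cosine), splits each score vector with [split_threshold()], and returns
#' the intersection of the per-view high-score sets. If the intersection has
#' fewer than `min_genes` genes, the fallback ranks genes by their mean rank
#' across views and keeps the median per-view set size, with a warning.
#'
#' @param X Genes-by-cells matrix (the same matrix the similarities were
#'   computed on).
#' @param sims Named list of symmetric similarity matrices; correlation-based
#'   ones are clipped to nonnegative internally.
#' @param direction `"ascending"` (default) keeps genes with *low* Laplacian
#'   scores, the locality-preserving (marker-like) direction for the
#'   `(f'Lf)/(f'Df)` score used here; `"descending"` keeps high scores, the
#'   informative direction for smoothness-type score variants.
#' @param min_genes Smallest acceptable intersection before the fallback.
#' @return A list of class `gene_selection`: `genes` (integer indices into
#'   rows of `X`), `scores` (p-by-views matrix), `splits` (per-view
#'   `gene_split`), `fallback` (logical).
#' @export
select_genes <- function(X, sims, direction = c("ascending", "descending"),
                         min_genes = 10) {
  direction <- match.arg(direction)
  decreasing <- direction == "descending"
  stopifnot(length(sims) >= 1)
  scores <- vapply(sims, function(S) laplacian_score(X, clip_nonnegative(S)),
                   numeric(nrow(X)))
  splits <- apply(scores, 2, split_threshold, decreasing = decreasing,
                  simplify = FALSE)
  sel <- Reduce(intersect, lapply(splits, `[[`, "g1"))
  fallback <- length(sel) < min_genes
  if (fallback) {
    rk <- apply(scores, 2, function(v) rank(if (decreasing) -v else v))
    target <- round(stats::median(vapply(splits, `[[`, 0L, "size")))
    sel <- sort(order(rowMeans(rk))[seq_len(target)])
    warning("gene-set intersection had fewer than ", min_genes,
            " genes; falling back to mean-rank selection of ", target, " genes")
  }
  structure(list(genes = sel, scores = scores, splits = splits,
                 fallback = fallback), class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("Gene selection across", ncol(x$scores), "similarity views\n")
  cat("  per-view set sizes:",
      paste(vapply(x$splits, `[[`, 0L, "size"), collapse = ", "), "\n")
  cat("  selected genes:", length(x$genes),
      if (x$fallback) "(mean-rank fallback)" else "(intersection)", "\n")
  invisible(x)
}
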