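#' Kruskal-Wallis differential expression screen
#'
#' Applies the Kruskal-Wallis rank-sum test (with tie correction, chi-square
#' approximation, df = groups - 1) to every gene against the supplied cluster
#' labels, via `stats::kruskal.test`. Genes identical across all cells give
#' H = 0, p = 1. The table is sorted by ascending p-value; significance uses
#' the raw p-value cutoff `alpha`, with a Benjamini-Hochberg adjusted column
#' reported alongside.
#'
#' @param X Genes-by-cells expression matrix.
#' @param labels Cluster labels, one per cell; every group needs >= 2 cells.
#' @param alpha Raw p-value cutoff for the `significant` flag.
#' @return A `data.frame` of class `deg_table`: `gene_id`, `h_statistic`,
#'   `p_value`, `p_adjusted`, `rank`, `significant`, sorted by p-value.
#' @export
kruskal_wallis_deg <- function(X, labels, alpha = 0.01) {
  labels <- as_label_vector(labels)
  if (length(labels) != ncol(X)) stop("labels must match the number of cells")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 cells; group(s) ",
                           paste(names(sizes)[sizes < 2], collapse = ", "),
                           " too small")
  g <- factor(labels)
  res <- apply(X, 1, function(f) {
    if (all(f == f[1])) return(c(0, 1))
    kt <- stats::kruskal.test(f, g)
    c(unname(kt$statistic), kt$p.value)
  })
  ids <- if (is.null(rownames(X))) paste0("gene", seq_len(nrow(X))) else rownames(X)
  tab <- data.frame(gene_id = ids, h_statistic = res[1, ], p_value = res[2, ],
                    p_adjusted = stats::p.adjust(res[2, ], "BH"),
                    row.names = NULL)
  tab <- tab[order(tab$p_value, tab$gene_id), ]
  tab$rank <- seq_len(nrow(tab))
  tab$significant <- tab$p_value < alpha
  rownames(tab) <- NULL
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Heat map of the top differentially expressed genes
#'
#' Plots the expression of the `top_n` lowest-p genes, cells ordered by
#' cluster, using `pheatmap` when available and base `image()` otherwise.
#'
#' @param X Expression matrix. @param labels Cluster labels.
#' @param deg A `deg_table` from [kruskal_wallis_deg()].
#' @param top_n Number of genes to show.
#' @param filename Optional file to write the plot to (pheatmap only).
#' @return The plotted submatrix, invisibly.
#' @export
plot_deg_heatmap <- function(X, labels, deg, top_n = 50, filename = NA) {
  labels <- as_label_vector(labels)
  genes <- utils::head(deg$gene_id, top_n)
  ord <- order(labels)
  sub <- log1p(X[genes, ord, drop = FALSE])
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    ann <- data.frame(cluster = factor(labels[ord]),
                      row.names = colnames(sub))
    pheatmap::pheatmap(sub, cluster_cols = FALSE, show_colnames = FALSE,
                       annotation_col = ann, filename = filename)
  } else {
    graphics::image(t(sub), main = "Top DEGs", axes = FALSE)
  }
  invisible(sub)
}

row_normalize_P <- function(E) {
  P <- E
  diag(P) <- 0
  rs <- rowSums(P)
  P[rs > 0, ] <- P[rs > 0, , drop = FALSE] / rs[rs > 0]
  P <- (P + t(P)) / (2 * nrow(P))
  pmax(P, .Machine$double.xmin)
}

# Minimal t-SNE gradient loop on a precomputed joint-probability matrix.
# Standard Kullback-Leibler gradient with Student-t low-dimensional kernel,
# momentum, and early exaggeration; used when the affinity itself plays the
# role of P, which off-the-shelf t-SNE front ends do not accept.
tsne_from_P <- function(P, dims = 2, max_iter = 500, eta = 100,
                        exaggeration = 4, seed = 1) {
  n <- nrow(P)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  Yc <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  inc <- matrix(0, n, dims)
  Pexp <- P * exaggeration
  for (it in seq_len(max_iter)) {
    Pt <- if (it <= 100) Pexp else P
    d2 <- as.matrix(stats::dist(Yc))^2
    W <- 1 / (1 + d2)
    diag(W) <- 0
    Q <- pmax(W / sum(W), .Machine$double.xmin)
    G <- 4 * ((Pt - Q) * W)
    grad <- (diag(rowSums(G)) - G) %*% Yc
    mom <- if (it <= 250) 0.5 else 0.8
    inc <- mom * inc - eta * grad
    Yc <- Yc + inc
    Yc <- sweep(Yc, 2, colMeans(Yc))
  }
  Yc
}

#' 2D embedding of cells from a learned similarity
#'
#' Embeds cells with a modified t-SNE that uses the learned similarity
#' directly: the enhanced affinity is row-normalized and symmetrized into the
#' joint-probability matrix driving the embedding (`mode = "affinity"`,
#' default), skipping the usual Gaussian-kernel perplexity calibration.
#' Alternatively (`mode = "distance"`) the similarity is converted to a
#' distance `1 - E/max(E)` and passed through standard t-SNE (Rtsne when
#' installed, otherwise the internal gradient loop on a perplexity-free
#' kernel). With fewer than 5 cells the top-2 spectral coordinates are
#' returned instead, with a warning.
#'
#' @param E Symmetric nonnegative similarity matrix.
#' @param labels Optional labels used only for plotting.
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @param mode `"affinity"` or `"distance"`.
#' @param perplexity Perplexity for the `"distance"` mode.
#' @param plot Draw a scatter plot colored by `labels`?
#' @return An n-by-2 coordinate matrix.
#' @export
visualize_similarity <- function(E, labels = NULL, seed = 1,
                                 mode = c("affinity", "distance"),
                                 perplexity = 30, plot = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(E)
  if (n < 5) {
    warning("fewer than 5 cells: returning top-2 spectral coordinates")
    L <- normalized_laplacian(E)
    eig <- eigen(L, symmetric = TRUE)
    coords <- eig$vectors[, n:max(1, n - 1), drop = FALSE]
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
  } else if (mode == "affinity") {
    coords <- tsne_from_P(row_normalize_P(E), seed = seed)
  } else {
    D <- 1 - E / max(E)
    diag(D) <- 0
    if (requireNamespace("Rtsne", quietly = TRUE)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old))
      set.seed(seed)
      coords <- Rtsne::Rtsne(stats::as.dist(D), is_distance = TRUE,
                             perplexity = min(perplexity, (n - 1) %/% 3),
                             theta = 0, pca = FALSE)$Y
    } else {
      W <- exp(-as.matrix(D)^2)
      diag(W) <- 0
      coords <- tsne_from_P(row_normalize_P(W), seed = seed)
    }
  }
  rownames(coords) <- rownames(E)
  colnames(coords) <- c("dim1", "dim2")
  if (plot) {
    col <- if (is.null(labels)) 1 else as_label_vector(labels)
    graphics::plot(coords, col = col, pch = 19,
                   xlab = "dim 1", ylab = "dim 2",
                   main = "Similarity embedding")
  }
  coords
}
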