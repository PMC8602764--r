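#' Configuration for the full clustering pipeline
#'
#' @param rho_over_lambda Data-weight ratio of the sparse subspace solver.
#' @param K Number of clusters, or `"auto"` to estimate by the eigengap.
#' @param k Enhancement neighborhood size; `NULL` uses [choose_k()].
#' @param seed Integer seed for the k-means stage.
#' @param gene_selection_direction `"ascending"` (low Laplacian scores kept;
#'   see [select_genes()]) or `"descending"`.
#' @param similarity_subset Which classical similarities to use alongside the
#'   sparse affinity for gene selection and enhancement; non-empty subset of
#'   `c("pearson", "spearman", "cosine")`, all three by default.
#' @param max_iter,tol ADMM controls, see [ssr_config()].
#' @return A list of class `ssre_config`.
#' @export
ssre_config <- function(rho_over_lambda = 10, K = "auto", k = NULL, seed = 1,
                        gene_selection_direction = "ascending",
                        similarity_subset = c("pearson", "spearman", "cosine"),
                        max_iter = 200, tol = 1e-6) {
  similarity_subset <- match.arg(similarity_subset,
                                 c("pearson", "spearman", "cosine"),
                                 several.ok = TRUE)
  if (!identical(K, "auto")) stopifnot(is.numeric(K), K >= 2)
  structure(list(rho_over_lambda = rho_over_lambda, K = K, k = k, seed = seed,
                 gene_selection_direction = gene_selection_direction,
                 similarity_subset = similarity_subset,
                 max_iter = max_iter, tol = tol),
            class = "ssre_config")
}

pairwise_sim_list <- function(Xn, subset) {
  fns <- list(pearson = pearson_similarity, spearman = spearman_similarity,
              cosine = cosine_similarity)
  lapply(fns[subset], function(f) f(Xn))
}

#' Run the full similarity-learning clustering pipeline
#'
#' Executes, in order: zero-gene filtering, per-cell L2 normalization, a
#' preliminary sparse subspace representation, Laplacian-score gene selection
#' under the sparse affinity plus the chosen classical similarities
#' (intersection of per-view top sets), re-normalization on the selected
#' genes, recomputation of all similarities, common-neighbor enhancement of
#' the sparse affinity, and spectral clustering with the given or
#' eigengap-estimated number of clusters. When reference labels are supplied,
#' NMI and ARI are reported.
#'
#' @param X Genes-by-cells matrix, or a path readable by [read_expression()].
#' @param config An [ssre_config()].
#' @param true_labels Optional reference labels for evaluation.
#' @return A list of class `ssre_result`: `labels`, `K_used`, `K_estimated`,
#'   `E` (enhanced similarity), `sim_sparse`, `selected_genes` (ids),
#'   `gene_selection`, `enhancement` (mask/imputation diagnostics),
#'   `ssr_fit`, `metrics` (NMI/ARI or NULL), `config`.
#' @examples
#' toy <- make_fixture("three_block_toy")
#' res <- run_pipeline(toy$X, ssre_config(K = 3, seed = 1))
#' ari(res$labels, toy$labels)
#' @export
run_pipeline <- function(X, config = ssre_config(), true_labels = NULL) {
  if (is.character(X)) X <- read_expression(X)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  Xf <- stage("filter", filter_zero_genes(X))
  Xn <- stage("normalize", l2_normalize_cells(Xf))
  scfg <- ssr_config(config$rho_over_lambda, config$max_iter, config$tol)
  fit0 <- stage("preliminary-ssr", solve_ssr(Xn, scfg))
  sims0 <- c(list(ssr = symmetrize_ssr(fit0)),
             stage("similarities", pairwise_sim_list(Xn, config$similarity_subset)))
  gsel <- stage("gene-selection",
                select_genes(Xn, sims0, direction = config$gene_selection_direction))
  Xs <- stage("renormalize", l2_normalize_cells(Xf[gsel$genes, , drop = FALSE]))
  fit <- stage("ssr", solve_ssr(Xs, scfg))
  sim_sparse <- symmetrize_ssr(fit)
  pair <- stage("similarities", pairwise_sim_list(Xs, config$similarity_subset))
  enh <- stage("enhancement", enhance_similarity(sim_sparse, pair, k = config$k))
  K_est <- stage("eigengap", estimate_k_eigengap(enh$E))
  K_used <- if (identical(config$K, "auto")) K_est else as.integer(config$K)
  cl <- stage("spectral-clustering",
              spectral_cluster(enh$E, K_used, seed = config$seed))
  metrics <- NULL
  if (!is.null(true_labels)) {
    true_labels <- as_label_vector(true_labels)
    metrics <- list(nmi = nmi(true_labels, cl$labels),
                    ari = ari(true_labels, cl$labels))
  }
  structure(list(labels = cl$labels, K_used = K_used, K_estimated = K_est,
                 E = enh$E, sim_sparse = sim_sparse,
                 selected_genes = rownames(Xf)[gsel$genes],
                 gene_selection = gsel,
                 enhancement = enh[c("mask", "k", "n_imputed")],
                 ssr_fit = fit, metrics = metrics, config = config),
            class = "ssre_result")
}

#' @export
print.ssre_result <- function(x, ...) {
  cat("SSRE clustering of", length(x$labels), "cells\n")
  cat("  selected genes:", length(x$selected_genes),
      " | enhancement k:", x$enhancement$k,
      " imputed edges:", x$enhancement$n_imputed, "\n")
  cat("  K used:", x$K_used, " (eigengap estimate:", x$K_estimated, ")\n")
  print(table(cluster = x$labels))
  if (!is.null(x$metrics))
    cat("  NMI:", round(x$metrics$nmi, 4), " ARI:", round(x$metrics$ari, 4), "\n")
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes cluster labels (CSV), the enhanced similarity (Matrix Market), the
#' selected gene list, and a JSON run report (K, metrics, seed, config).
#'
#' @param result An `ssre_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells <- colnames(result$E)
  if (is.null(cells)) cells <- paste0("cell", seq_along(result$labels))
  utils::write.csv(data.frame(cell_id = cells, cluster = result$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(result$E, sparse = TRUE, doDiag = FALSE),
                  file.path(dir, "enhanced_similarity.mtx"))
  writeLines(result$selected_genes, file.path(dir, "selected_genes.txt"))
  report <- list(n_cells = length(result$labels), K_used = result$K_used,
                 K_estimated = result$K_estimated,
                 n_selected_genes = length(result$selected_genes),
                 n_imputed = result$enhancement$n_imputed,
                 metrics = result$metrics,
                 config = result$config[setdiff(names(result$config), "k")])
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
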