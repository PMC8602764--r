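#' Configuration for the Splatter-style count simulator
#'
#' Defines a simplified generative model for grouped scRNA-seq counts:
#' log-normal base gene means, per-group multiplicative differential
#' expression on a random gene subset, log-normal cell size factors,
#' negative-binomial sampling, and logistic dropout keyed to each entry's
#' log mean. The defaults mirror a three-population design with unbalanced
#' group proportions (0.65, 0.25, 0.1).
#'
#' @param n_cells Number of cells.
#' @param group_prob Group proportions; positive, summing to 1.
#' @param n_genes Number of genes (default 2000, comfortably above the gene
#'   selection window's minimum).
#' @param de_prob Fraction of genes differentially expressed in each group.
#' @param de_factor_range Range of multiplicative DE effect sizes; half of
#'   the DE genes are down-regulated (factor inverted).
#' @param dropout_mid Location of the logistic dropout curve on the log-mean
#'   scale; `-Inf` disables dropout. Larger values give more zeros.
#' @param dropout_shape Slope of the dropout logistic (negative: weakly
#'   expressed entries drop out more).
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param depth Overall expression depth multiplier.
#' @param lib_sigma Log-normal sd of per-cell size factors.
#' @param seed Integer seed; every draw is reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1000, group_prob = c(0.65, 0.25, 0.1),
                       n_genes = 2000, de_prob = 0.1,
                       de_factor_range = c(1.5, 5), dropout_mid = -Inf,
                       dropout_shape = -1, nb_dispersion = 0.25,
                       depth = 5, lib_sigma = 0.25, seed = 1) {
  stopifnot(n_cells >= 2, all(group_prob > 0),
            abs(sum(group_prob) - 1) < 1e-9, n_genes >= 20,
            de_prob > 0, de_prob <= 1, nb_dispersion > 0, depth > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate grouped single-cell counts
#'
#' Draws a genes-by-cells count matrix with known group labels from the
#' generative model described in [sim_config()]:
#' base means `mu_g ~ LogNormal(0, 1)`, group factors applied to a `de_prob`
#' fraction of genes per group, cell size factors
#' `s_c ~ LogNormal(0, lib_sigma)`, entry means
#' `m_gc = depth * mu_g * f_g(group(c)) * s_c`, counts
#' `~ NegBinomial(mean = m_gc, size = 1/nb_dispersion)`, then zeros injected
#' with probability `plogis(dropout_shape * (log(m_gc) - dropout_mid))`
#' evaluated as `1 / (1 + exp(log(m_gc) - dropout_mid))` for the default
#' slope of -1, so weakly expressed entries drop out more and raising
#' `dropout_mid` monotonically increases sparsity.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_data`: `counts` (genes x cells, with
#'   dimnames), `labels` (integer groups), `de_genes` (per-group DE index
#'   list), `sparsity` (achieved zero fraction), `cfg`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  p <- cfg$n_genes; n <- cfg$n_cells; g <- length(cfg$group_prob)
  labels <- sample.int(g, n, replace = TRUE, prob = cfg$group_prob)
  if (length(unique(labels)) < g) {
    warning("a group drew 0 cells; resampling once")
    labels <- sample.int(g, n, replace = TRUE, prob = cfg$group_prob)
  }
  mu <- stats::rlnorm(p, meanlog = 0, sdlog = 1)
  de_genes <- vector("list", g)
  fac <- matrix(1, p, g)
  for (k in seq_len(g)) {
    idx <- sample.int(p, round(cfg$de_prob * p))
    f <- stats::runif(length(idx), cfg$de_factor_range[1], cfg$de_factor_range[2])
    down <- stats::runif(length(idx)) < 0.5
    f[down] <- 1 / f[down]
    fac[idx, k] <- f
    de_genes[[k]] <- sort(idx)
  }
  s <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$lib_sigma)
  M <- cfg$depth * (mu * fac[, labels]) * rep(s, each = p)
  counts <- matrix(stats::rnbinom(p * n, mu = M, size = 1 / cfg$nb_dispersion), p, n)
  if (is.finite(cfg$dropout_mid)) {
    pdrop <- stats::plogis(cfg$dropout_shape * (log(M) - cfg$dropout_mid))
    counts[stats::runif(p * n) < pdrop] <- 0
  }
  dimnames(counts) <- list(paste0("gene", seq_len(p)), paste0("cell", seq_len(n)))
  structure(list(counts = counts, labels = labels, de_genes = de_genes,
                 sparsity = mean(counts == 0), cfg = cfg),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Simulated counts:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  groups:", paste(table(x$labels), collapse = "/"),
      " sparsity:", round(x$sparsity, 3), "\n")
  invisible(x)
}

#' Calibrate dropout to a target zero fraction
#'
#' Bisection on `dropout_mid` until the achieved zero fraction of the seeded
#' simulation is within `tol` of `target_sparsity`. Fails with the attainable
#' floor when the target lies below the model's natural (no-dropout) zero
#' fraction.
#'
#' @param cfg A [sim_config()].
#' @param target_sparsity Desired zero fraction in (0, 1).
#' @param tol Acceptable absolute deviation (default 0.02, the reporting
#'   precision of the target values).
#' @param max_iter Bisection iterations.
#' @return The input config with `dropout_mid` set; attributes
#'   `achieved_sparsity` and `floor_sparsity` record the calibration.
#' @export
calibrate_dropout <- function(cfg, target_sparsity, tol = 0.02, max_iter = 40) {
  stopifnot(target_sparsity > 0, target_sparsity < 1)
  zero_frac <- function(mid) {
    cfg$dropout_mid <- mid
    simulate_counts(cfg)$sparsity
  }
  floor_s <- zero_frac(-Inf)
  if (target_sparsity < floor_s - tol)
    stop("target sparsity ", target_sparsity,
         " is below the no-dropout floor ", round(floor_s, 3))
  lo <- -10; hi <- 10
  while (zero_frac(hi) < target_sparsity && hi < 60) hi <- hi + 10
  achieved <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    achieved <- zero_frac(mid)
    if (abs(achieved - target_sparsity) <= tol / 2) break
    if (achieved < target_sparsity) lo <- mid else hi <- mid
  }
  if (abs(achieved - target_sparsity) > tol)
    warning("calibration stopped at achieved sparsity ", round(achieved, 3))
  cfg$dropout_mid <- mid
  attr(cfg, "achieved_sparsity") <- achieved
  attr(cfg, "floor_sparsity") <- floor_s
  cfg
}

#' Deterministic micro-datasets for tests and examples
#'
#' @param name One of `"two_identical_cells"` (two equal unit-norm columns),
#'   `"three_block_toy"` (30 cells in 3 well-separated groups),
#'   `"path_graph_toy"` (3 cells forming a similarity path), `"tiny_mixed"`
#'   (25 cells, 2 overlapping groups).
#' @return A list with `X` (genes x cells) and `labels` (integer vector, or
#'   `NULL` for the path toy).
#' @export
make_fixture <- function(name = c("two_identical_cells", "three_block_toy",
                                  "path_graph_toy", "tiny_mixed")) {
  name <- match.arg(name)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  switch(name,
    two_identical_cells = {
      x <- c(3, 4) / 5
      list(X = cbind(c1 = x, c2 = x), labels = c(1L, 1L))
    },
    three_block_toy = {
      set.seed(42)
      p <- 60; sizes <- c(12, 10, 8)
      labels <- rep(1:3, sizes)
      base <- matrix(0.05, p, 3)
      for (k in 1:3) base[((k - 1) * 20 + 1):(k * 20), k] <- 5
      X <- base[, labels] + matrix(stats::runif(p * 30, 0, 0.3), p)
      dimnames(X) <- list(paste0("g", 1:p), paste0("c", 1:30))
      list(X = X, labels = labels)
    },
    path_graph_toy = {
      X <- cbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(0, 0, 1))
      list(X = X, labels = NULL)
    },
    tiny_mixed = {
      set.seed(7)
      p <- 40; labels <- rep(1:2, c(13, 12))
      base <- matrix(1, p, 2); base[1:20, 1] <- 3; base[21:40, 2] <- 3
      X <- base[, labels] + matrix(stats::rnorm(p * 25, 0, 0.8), p)
      X[X < 0] <- 0
      dimnames(X) <- list(paste0("g", 1:p), paste0("c", 1:25))
      list(X = X, labels = labels)
    })
}
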