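test_that("Kruskal-Wallis screen matches the hand-computed two-group case", {
  X <- rbind(gA = c(1, 2, 3, 10, 11, 12), gB = rep(5, 6))
  labels <- rep(1:2, each = 3)
  tab <- kruskal_wallis_deg(X, labels)
  a <- tab[tab$gene_id == "gA", ]
  # fully separated ranks: H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  expect_equal(a$h_statistic, 27 / 7, tolerance = 1e-6)
  expect_equal(a$p_value, stats::pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(round(a$p_value, 4), 0.0495)
  b <- tab[tab$gene_id == "gB", ]
  expect_equal(b$h_statistic, 0)
  expect_equal(b$p_value, 1)
  expect_identical(tab$rank, 1:2)
})

test_that("the chi-square p-value agrees with a permutation test", {
  set.seed(50)
  n_per <- 15
  f <- c(rnorm(n_per, 0), rnorm(n_per, 1))
  labels <- rep(1:2, each = n_per)
  tab <- kruskal_wallis_deg(matrix(f, 1, dimnames = list("g", NULL)), labels)
  h_obs <- tab$h_statistic
  perm <- replicate(10000, {
    l <- sample(labels)
    unname(stats::kruskal.test(f, factor(l))$statistic)
  })
  p_perm <- mean(perm >= h_obs - 1e-12)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(tab$p_value - p_perm), 4 * mc_sd + 0.005)
})

test_that("the DEG table is invariant to permuting cells with their labels", {
  set.seed(51)
  X <- matrix(rpois(20 * 12, 5), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:12)))
  labels <- rep(1:3, each = 4)
  perm <- sample(12)
  t1 <- kruskal_wallis_deg(X, labels)
  t2 <- kruskal_wallis_deg(X[, perm], labels[perm])
  expect_equal(t1, t2)
  expect_error(kruskal_wallis_deg(X, c(rep(1, 11), 2)), "at least 2 cells")
})

test_that("similarity embedding separates blocks and is seed-deterministic", {
  set.seed(52)
  E <- block_sim(c(10, 8, 7), weight = 1, noise = 0.02)
  labels <- rep(1:3, c(10, 8, 7))
  y1 <- visualize_similarity(E, seed = 3)
  y2 <- visualize_similarity(E, seed = 3)
  expect_identical(y1, y2)
  # inter-block centroid distances exceed intra-block spread
  cent <- sapply(1:3, function(k) colMeans(y1[labels == k, , drop = FALSE]))
  spread <- mean(sapply(1:3, function(k) {
    mean(sqrt(rowSums(sweep(y1[labels == k, , drop = FALSE], 2, cent[, k])^2)))
  }))
  dmin <- min(dist(t(cent)))
  expect_gt(dmin, spread)
})

test_that("tiny inputs fall back to spectral coordinates with a warning", {
  E <- block_sim(c(2, 2), weight = 1)
  expect_warning(y <- visualize_similarity(E, seed = 1), "fewer than 5")
  expect_identical(dim(y), c(4L, 2L))
  yd <- visualize_similarity(block_sim(c(5, 5), weight = 1, noise = 0.05),
                             seed = 2, mode = "distance", perplexity = 2)
  expect_identical(dim(yd), c(10L, 2L))
})
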