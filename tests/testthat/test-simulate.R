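test_that("simulated group sizes follow the configured proportions", {
  sim <- simulate_counts(sim_config(n_cells = 1000, seed = 5))
  counts <- tabulate(sim$labels, 3)
  expect_true(all(abs(counts - c(650, 250, 100)) < 4 * sqrt(1000 * c(.65, .25, .1))))
  # chi-square sanity at large n
  big <- simulate_counts(sim_config(n_cells = 10000, n_genes = 50, seed = 6))
  p <- stats::chisq.test(tabulate(big$labels, 3),
                         p = c(0.65, 0.25, 0.1))$p.value
  expect_gt(p, 1e-4)
})

test_that("simulation is deterministic in the seed and leaves the RNG alone", {
  cfg <- sim_config(n_cells = 60, n_genes = 100, seed = 9)
  a <- simulate_counts(cfg)
  set.seed(123); before <- runif(1)
  b <- simulate_counts(cfg)
  set.seed(123); after <- runif(1)
  expect_identical(a$counts, b$counts)
  expect_identical(a$labels, b$labels)
  expect_identical(before, after)
})

test_that("sparsity is monotone in dropout_mid and dropout can be disabled", {
  cfg <- sim_config(n_cells = 80, n_genes = 300, seed = 10)
  mids <- c(-Inf, 0, 2, 4, 6)
  sp <- vapply(mids, function(m) {
    cfg$dropout_mid <- m
    simulate_counts(cfg)$sparsity
  }, 0)
  expect_true(all(diff(sp) >= 0))
  expect_lt(sp[1], 0.3)  # natural negative-binomial zero floor only
})

test_that("dropout calibration hits the target zero fraction", {
  cfg <- sim_config(n_cells = 150, n_genes = 500, seed = 11)
  for (target in c(0.61, 0.94)) {
    cal <- calibrate_dropout(cfg, target)
    achieved <- simulate_counts(cal)$sparsity
    expect_lt(abs(achieved - target), 0.02)
  }
  expect_error(calibrate_dropout(cfg, 0.01), "floor")
})

test_that("differential-expression factors are recoverable from group means", {
  cfg <- sim_config(n_cells = 800, n_genes = 300, seed = 12,
                    nb_dispersion = 0.05, lib_sigma = 0, depth = 50,
                    de_factor_range = c(4, 4))
  sim <- simulate_counts(cfg)
  de1 <- setdiff(sim$de_genes[[1]], unlist(sim$de_genes[2:3]))
  m1 <- rowMeans(sim$counts[de1, sim$labels == 1, drop = FALSE])
  m2 <- rowMeans(sim$counts[de1, sim$labels == 2, drop = FALSE])
  ratio <- m1 / m2
  # factors are 4 or 1/4; log-ratio magnitude should concentrate near log 4
  expect_equal(median(abs(log(ratio))), log(4), tolerance = 0.15)
})

test_that("fixtures are deterministic and match their contracts", {
  fx <- make_fixture("two_identical_cells")
  expect_equal(fx$X[, 1], fx$X[, 2])
  expect_equal(sum(fx$X[, 1]^2), 1)
  toy <- make_fixture("three_block_toy")
  expect_identical(dim(toy$X), c(60L, 30L))
  expect_identical(toy$labels, rep(1:3, c(12, 10, 8)))
  expect_identical(make_fixture("three_block_toy")$X, toy$X)
  expect_error(make_fixture("nope"))
})
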