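test_that("neighborhood size follows the 0.1n / 100 rule with a floor", {
  expect_equal(choose_k(90), 9L)
  expect_equal(choose_k(6000), 100L)
  expect_equal(choose_k(5), 1L)
  expect_equal(choose_k(4999), 500L)
})

test_that("KNN indicator ranks raw similarities with deterministic ties", {
  S <- rbind(c(1, 0.9, 0.1, 0.5),
             c(0.9, 1, 0.2, 0.3),
             c(0.1, 0.2, 1, 0.4),
             c(0.5, 0.3, 0.4, 1))
  P <- knn_indicator(S, 1)
  expect_equal(which(P[1, ] == 1), 2L)
  expect_equal(rowSums(P), rep(1, 4))
  expect_equal(diag(P), rep(0L, 4))
  Pfull <- knn_indicator(S, 3)
  expect_true(all(Pfull[row(Pfull) != col(Pfull)] == 1L))
  # tie at the k-th value: smaller index wins
  St <- rbind(c(1, 0.5, 0.5, 0.1), c(0.5, 1, 0, 0), c(0.5, 0, 1, 0),
              c(0.1, 0, 0, 1))
  expect_equal(which(knn_indicator(St, 1)[1, ] == 1), 2L)
  expect_error(knn_indicator(S, 4), "k must be")
})

test_that("missing-value mask requires a zero sparse entry plus KNN support", {
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 0.5
  P1 <- matrix(0L, 3, 3); P1[1, 3] <- 1L
  P2 <- matrix(0L, 3, 3); P2[1, 2] <- 1L
  mask <- mark_missing(S, list(P1, P2))
  expect_equal(mask[1, 3], 1L)   # zero in S, supported by one indicator
  expect_equal(mask[1, 2], 0L)   # nonzero in S: never marked
  expect_equal(mask[3, 1], 0L)   # no indicator support
  expect_equal(diag(mask), rep(0L, 3))
})

test_that("path-graph imputation matches the hand-computed score", {
  # i - z - j with S(i,z) = 0.4, S(j,z) = 0.6, deg(z) = 2
  S <- matrix(0, 3, 3)
  S[1, 2] <- S[2, 1] <- 0.4
  S[2, 3] <- S[3, 2] <- 0.6
  mask <- matrix(0L, 3, 3); mask[1, 3] <- 1L
  I <- adamic_adar_impute(S, mask)
  expect_equal(I[1, 3], (0.4 + 0.6) / 2)
  expect_equal(sum(I != 0), 1)   # unmarked entries stay zero
  # no common neighbor: score is zero
  S2 <- matrix(0, 4, 4); S2[1, 2] <- S2[2, 1] <- 1; S2[3, 4] <- S2[4, 3] <- 1
  m2 <- matrix(0L, 4, 4); m2[1, 3] <- 1L
  expect_equal(adamic_adar_impute(S2, m2)[1, 3], 0)
})

test_that("vectorized imputation equals the literal triple loop", {
  set.seed(30)
  for (n in c(12, 30, 50)) {
    S <- random_sparse_sim(n, density = 0.25)
    P <- knn_indicator(matrix(runif(n * n), n), max(1, n %/% 10))
    mask <- mark_missing(S, list(P))
    expect_equal(adamic_adar_impute(S, mask), brute_adamic_adar(S, mask))
  }
})

test_that("enhancement adds similarity without removing any", {
  set.seed(31)
  S <- random_sparse_sim(25, density = 0.2)
  Sp <- list(p = matrix(runif(625), 25), q = matrix(runif(625), 25))
  enh <- enhance_similarity(S, Sp, k = 4)
  expect_true(all(enh$E >= S - 1e-12))
  expect_equal(enh$E, t(enh$E))
  expect_true(all(enh$E >= 0))
  expect_equal(diag(enh$E), rep(0, 25))
  if (sum(enh$mask) > 0) expect_gte(sum(enh$E != 0), sum(S != 0))
})

test_that("block-confined neighbors keep enhancement block-diagonal", {
  set.seed(32)
  sizes <- c(8, 7, 5)
  S <- block_sim(sizes, weight = 0.5)
  # sprinkle zeros inside blocks so there is something to impute
  S[2, 3] <- S[3, 2] <- 0
  blocks <- rep(seq_along(sizes), sizes)
  Scorr <- block_sim(sizes, weight = 1)
  enh <- enhance_similarity(S, list(corr = Scorr), k = 3)
  off_block <- outer(blocks, blocks, "!=")
  expect_true(all(enh$E[off_block] == 0))
  expect_gt(enh$E[2, 3], 0)   # the deleted within-block edge was imputed
})
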