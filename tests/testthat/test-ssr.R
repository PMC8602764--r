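test_that("the adaptive scale rho is the minimax off-diagonal cosine", {
  G <- rbind(c(1, 0.9, 0.8), c(0.9, 1, 0.7), c(0.8, 0.7, 1))
  X <- cells_from_gram(G)
  expect_equal(compute_rho(X), 0.8, tolerance = 1e-10)
  expect_error(compute_rho(diag(2)), "orthogonal")
  X2 <- matrix(c(3, 4) / 5, 2, 2)
  expect_equal(compute_rho(X2), 1)
})

test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(0, 5), 0)
  expect_equal(soft_threshold(c(-3, 0.2, 4), 0.5), c(-2.5, 0, 3.5))
})

test_that("two identical cells recover the scalar lasso closed form", {
  fx <- make_fixture("two_identical_cells")
  fit <- solve_ssr(fx$X, ssr_config(rho_over_lambda = 10, max_iter = 5000,
                                    tol = 1e-12))
  # minimize (w/2)(1 - c)^2 + |c| with w = 10 has optimum c = 1 - 1/w
  expect_equal(fit$C[1, 2], 0.9, tolerance = 1e-6)
  expect_equal(fit$C[2, 1], 0.9, tolerance = 1e-6)
  expect_equal(unname(diag(fit$C)), c(0, 0))
})

test_that("ADMM matches an independent coordinate-descent lasso solver", {
  set.seed(3)
  X <- l2_normalize_cells(matrix(rexp(40 * 15), 40, 15))
  rho <- compute_rho(X)
  w <- 10 / rho
  fit <- solve_ssr(X, ssr_config(10, max_iter = 2000, tol = 1e-10))
  C_cd <- cd_ssr(X, w)
  obj_admm <- ssr_objective(X, fit$C, w)
  obj_cd <- ssr_objective(X, C_cd, w)
  expect_lt(abs(obj_admm - obj_cd) / abs(obj_cd), 1e-4)
})

test_that("mutually orthogonal cells with a weak data term give C = 0", {
  X <- diag(4)
  fit <- suppressWarnings(
    solve_ssr(X, ssr_config(rho_over_lambda = 0.5, max_iter = 500), rho = 1))
  expect_equal(max(abs(fit$C)), 0)
})

test_that("the solution depends on the data only through the Gram matrix", {
  set.seed(4)
  X <- l2_normalize_cells(matrix(rexp(30 * 8), 30, 8))
  Q <- qr.Q(qr(matrix(rnorm(30 * 30), 30, 30)))
  cfg <- ssr_config(10, max_iter = 1000, tol = 1e-10)
  f1 <- solve_ssr(X, cfg)
  f2 <- solve_ssr(Q %*% X, cfg)
  expect_equal(f1$C, f2$C, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("primal residual decreases to tolerance on well-conditioned input", {
  set.seed(5)
  X <- l2_normalize_cells(matrix(rexp(25 * 10), 25, 10))
  fit <- solve_ssr(X, ssr_config(10, max_iter = 2000, tol = 1e-8))
  expect_true(fit$converged)
  tail_r <- utils::tail(fit$residuals, 10)
  expect_true(all(diff(tail_r) <= 1e-10))
})

test_that("symmetrization folds signed coefficients into nonnegative affinity", {
  C <- rbind(c(0, 0.3), c(0.1, 0))
  expect_equal(symmetrize_ssr(C), rbind(c(0, 0.4), c(0.4, 0)))
  expect_equal(symmetrize_ssr(matrix(0, 3, 3)), matrix(0, 3, 3))
  C2 <- matrix(0, 2, 2); C2[1, 2] <- -0.2; C2[2, 1] <- 0.5
  expect_equal(symmetrize_ssr(C2)[1, 2], 0.7)
  set.seed(6)
  C3 <- matrix(rnorm(25), 5, 5); diag(C3) <- 0
  S <- symmetrize_ssr(C3)
  expect_equal(S, t(S))
  expect_true(all(S >= 0))
  expect_equal(diag(S), rep(0, 5))
})
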