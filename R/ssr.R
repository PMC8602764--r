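#' Adaptive sparsity scale from the cell-cell Gram matrix
#'
#' For an L2-normalized matrix X the Gram matrix M = t(X) %*% X holds cosine
#' similarities between cells. The scale rho = min over cells j of the largest
#' off-diagonal similarity in column j adapts the lasso penalty to how
#' mutually representable the cells are: tightly related cells (rho near 1)
#' tolerate a stronger penalty than loosely related ones.
#'
#' @param X L2-normalized genes-by-cells matrix (see [l2_normalize_cells()]).
#' @return Positive scalar `rho` (at most 1). The self-similarity diagonal is
#'   excluded, otherwise the minimax would always be 1.
#' @export
compute_rho <- function(X) {
  n <- ncol(X)
  if (n < 2) stop("need at least 2 cells")
  M <- crossprod(X)
  diag(M) <- -Inf
  rho <- min(apply(M, 2, max))
  if (rho <= 0)
    stop("rho <= 0: some cell is orthogonal or anticorrelated to every other ",
         "cell; inspect the data (rho = ", format(rho), ")")
  rho
}

#' Elementwise soft-thresholding operator
#'
#' The proximal operator of the L1 norm: `sign(v) * pmax(abs(v) - tau, 0)`.
#' This is the closed-form solution of the coefficient subproblem in the
#' ADMM splitting used by [solve_ssr()].
#'
#' @param v Numeric vector or matrix.
#' @param tau Nonnegative threshold.
#' @return Shrunken values, same shape as `v`.
#' @export
soft_threshold <- function(v, tau) {
  stopifnot(tau >= 0)
  sign(v) * pmax(abs(v) - tau, 0)
}

#' Configuration for the sparse subspace solver
#'
#' @param rho_over_lambda Ratio controlling the data-fit weight relative to
#'   the adaptive scale `rho`; the effective lasso data weight is
#'   `rho_over_lambda / rho`. Clustering quality is flat for values roughly
#'   between 6 and 20; 10 is the default.
#' @param max_iter Maximum ADMM iterations.
#' @param tol Convergence tolerance on the relative primal residual
#'   `||Z - C||_F / max(1, ||C||_F)`.
#' @return A list of class `ssr_config`.
#' @export
ssr_config <- function(rho_over_lambda = 10, max_iter = 200, tol = 1e-6) {
  stopifnot(rho_over_lambda > 0, max_iter >= 1, tol > 0)
  structure(list(rho_over_lambda = rho_over_lambda, max_iter = max_iter,
                 tol = tol), class = "ssr_config")
}

#' Sparse subspace representation of cells by ADMM
#'
#' Finds an n-by-n coefficient matrix C with zero diagonal that approximately
#' minimizes
#' \deqn{\frac{w}{2}\|X - XC\|_F^2 + \|C\|_1, \quad w = \texttt{rho\_over\_lambda}/\rho,}
#' so that each cell is written as a sparse linear combination of the other
#' cells. Under the subspace assumption the nonzero coefficients connect cells
#' of the same type. The problem is split as Z = C and solved by scaled ADMM:
#' a linear solve in Z against the cached cell-cell Gram matrix, an
#' elementwise soft-threshold in C (diagonal re-zeroed), and a dual ascent
#' step, with the ADMM penalty set equal to the data weight `w`.
#'
#' @param X L2-normalized genes-by-cells matrix.
#' @param config An [ssr_config()].
#' @param rho Optional precomputed adaptive scale; computed by
#'   [compute_rho()] when `NULL`.
#' @return A list of class `ssr_fit` with elements `C` (coefficients, zero
#'   diagonal), `w` (data weight used), `rho`, `iterations`, `converged`, and
#'   `residuals` (relative primal residual per iteration).
#' @export
solve_ssr <- function(X, config = ssr_config(), rho = NULL) {
  n <- ncol(X)
  if (is.null(rho)) rho <- compute_rho(X)
  w <- config$rho_over_lambda / rho     # 1/lambda = 1/gamma
  gamma <- 1 / w
  G <- crossprod(X)                     # n x n Gram, cached
  # Z-update solves (G + I) Z = G + C - Y/w; factor once.
  H <- chol2inv(chol(G + diag(n)))
  HG <- H %*% G
  C <- matrix(0, n, n)
  Y <- matrix(0, n, n)
  residuals <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    Z <- HG + H %*% (C - Y * gamma)
    C <- soft_threshold(Z + gamma * Y, gamma)
    diag(C) <- 0
    Y <- Y + w * (Z - C)
    r <- norm(Z - C, "F") / max(1, norm(C, "F"))
    residuals <- c(residuals, r)
    if (r <= config$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ADMM reached max_iter = ", config$max_iter,
            " with relative primal residual ", format(r, digits = 3))
  dimnames(C) <- list(colnames(X), colnames(X))
  structure(list(C = C, w = w, rho = rho, iterations = length(residuals),
                 converged = converged, residuals = residuals),
            class = "ssr_fit")
}

#' @export
print.ssr_fit <- function(x, ...) {
  cat("Sparse subspace representation fit\n")
  cat("  cells:", ncol(x$C), " data weight w:", format(x$w, digits = 4),
      " rho:", format(x$rho, digits = 4), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  nonzero coefficients:", sum(x$C != 0), "\n")
  invisible(x)
}

#' Symmetrize sparse coefficients into a similarity matrix
#'
#' Combines the directed representation coefficients into a symmetric
#' nonnegative cell-to-cell affinity: `S[i, j] = |C[i, j]| + |C[j, i]|`.
#' Absolute values guarantee nonnegativity, which raw coefficient sums do not.
#'
#' @param C Coefficient matrix from [solve_ssr()] (an `ssr_fit` or a bare
#'   matrix with zero diagonal).
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
symmetrize_ssr <- function(C) {
  if (inherits(C, "ssr_fit")) C <- C$C
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  S <- abs(C) + t(abs(C))
  diag(S) <- 0
  S
}

#' Objective value of the sparse subspace program
#'
#' Evaluates `(w/2) * ||X - XC||_F^2 + ||C||_1`, useful for comparing solver
#' output against independent lasso solvers.
#'
#' @param X Data matrix. @param C Coefficient matrix. @param w Data weight.
#' @return Scalar objective value.
#' @export
ssr_objective <- function(X, C, w) {
  (w / 2) * norm(X - X %*% C, "F")^2 + sum(abs(C))
}
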