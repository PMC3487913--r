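#' Objective value of the regularized factorization
#'
#' `F(W, A) = ||X - W A'||_F^2 + lam * J(W)` where `J` is the penalty of
#' the regularizer (see [Regularizer-class]).  The proximal terms used by
#' the block updates are *not* part of the objective; they belong to the
#' subproblems only.
#'
#' @param X non-negative data matrix (`n x m`).
#' @param model an [NMFModel-class] (or [NMFFit-class]).
#' @param reg a [Regularizer-class]; default none.
#' @return non-negative scalar.
#' @export
objectiveValue <- function(X, model, reg = regNone()) {
  W <- model@W; A <- model@A
  if (nrow(X) != nrow(W) || ncol(X) != nrow(A))
    stop("dimensions of 'X' do not match the model")
  if (any(W < 0) || any(A < 0))
    stop("model factors must be non-negative")
  sum((X - W %*% t(A))^2) + reg@lam * regPenalty(W, reg)
}

#' Fraction of (near-)zero entries in a matrix
#'
#' The solver's truncation updates produce exact zeros, so the default
#' threshold is 0; a positive `eps` counts entries `<= eps` instead.
#'
#' @param W numeric matrix.
#' @param eps non-negative threshold (default 0).
#' @return fraction in `[0, 1]`.
#' @export
sparsityFraction <- function(W, eps = 0) {
  if (length(W) == 0L) stop("empty matrix")
  if (eps < 0) stop("'eps' must be non-negative")
  mean(W <= eps)
}

#' First-order (KKT) residuals of a factor model
#'
#' Diagnostics for how far a model is from a critical point of the
#' regularized objective, the quantities the solver traces per sweep.
#'
#' `kktResidualW()` forms the gradient
#' `G = -2 (X - W A') A + lam * dJ/dW` and returns the max-norm of
#' `pmin(W, G)` elementwise: zero where either the coordinate is at an
#' optimal interior point (`G = 0`) or pinned at the boundary with
#' non-negative gradient.  `kktResidualA()` evaluates, for each mixing
#' column, the gradient `2 (A W'W - X'W)[, l]` and returns the largest
#' [simplexOptimalityGap()] across columns.  Both approach zero at a
#' critical point.
#'
#' @inheritParams objectiveValue
#' @return non-negative scalar.
#' @export
kktResidualW <- function(X, model, reg = regNone()) {
  W <- model@W; A <- model@A
  G <- -2 * (X - W %*% t(A)) %*% A + regGradient(W, reg)
  max(abs(pmin(W, G)))
}

#' @rdname kktResidualW
#' @export
kktResidualA <- function(X, model) {
  W <- model@W; A <- model@A
  D <- 2 * (A %*% crossprod(W) - crossprod(X, W))
  gaps <- vapply(seq_len(ncol(A)),
                 function(l) simplexOptimalityGap(D[, l], A[, l]),
                 numeric(1))
  max(gaps)
}
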