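#' Exact block updates of the block-coordinate descent sweep
#'
#' These are the per-block minimizers that the [regnmf()] sweep cycles
#' through.  `R` is always the rank-one residual: the data matrix minus
#' the reconstruction of every component *except* the one being updated
#' (callers add `w_l %*% t(a_l)` back before updating component `l`).
#' Each update minimizes its block objective *exactly*, including a
#' proximal term `tau * ||. - previous||^2` that keeps the subproblem
#' strictly convex, so the global objective can never increase.
#'
#' `updateMixingColumn()` minimizes
#' `||R - w a'||_F^2 + tauA ||a - aPrev||^2` over the alpha-simplex.
#' The quadratic form is `(||w||^2 + tauA) I`, i.e. diagonal, so the
#' minimizer is [projectSimplex()] applied to
#' `c = (R'w + tauA aPrev) / (||w||^2 + tauA)`.  `tauA > 0` is required:
#' it keeps the block strictly convex even when a base vector degenerates
#' to zero (in which case the update returns `aPrev`).
#'
#' @param R residual matrix `n x m` excluding the updated component.
#' @param w current base vector (length `n`) of the component.
#' @param aPrev previous mixing column (length `m`), feasible.
#' @param alpha simplex scale.
#' @param tauA,tauW proximal weights (`tauA > 0`; `tauW >= 0`, but must be
#'   `> 0` whenever `a = 0` would make the component block non-strictly
#'   convex).
#' @return the updated block (vector, or matrix for
#'   `updateComponentRelated()`).
#' @name blockUpdates
#' @export
updateMixingColumn <- function(R, w, aPrev, alpha, tauA) {
  if (tauA <= 0) stop("'tauA' must be positive")
  if (nrow(R) != length(w) || ncol(R) != length(aPrev))
    stop("dimension mismatch between R, w, aPrev")
  denom <- sum(w^2) + tauA
  cvec <- (drop(crossprod(R, w)) + tauA * aPrev) / denom
  projectSimplex(cvec, alpha)
}

#' @rdname blockUpdates
#' @param a current mixing column (length `m`) of the component.
#' @param wPrev previous base vector (length `n`).
#' @param lam regularization weight.
#' @details `updateComponentL1()` minimizes
#'   `||R - w a'||_F^2 + lam * sum(w) + tauW ||w - wPrev||^2` over
#'   `w >= 0`.  The KKT conditions give the closed form
#'   `w_i = max(0, (R a)_i + tauW wPrev_i - lam/2) / (||a||^2 + tauW)`:
#'   soft thresholding with exact zeros.  The threshold is `lam/2`
#'   because the reconstruction term carries no 1/2 factor; the
#'   finite-difference tests pin this convention against
#'   [objectiveValue()] and the KKT residuals.
#' @export
updateComponentL1 <- function(R, a, wPrev, lam, tauW) {
  if (nrow(R) != length(wPrev) || ncol(R) != length(a))
    stop("dimension mismatch between R, a, wPrev")
  denom <- sum(a^2) + tauW
  if (denom == 0)
    stop("'a' is zero and 'tauW' is zero: component block not strictly convex")
  pmax(0, (drop(R %*% a) + tauW * wPrev - lam / 2)) / denom
}

#' @rdname blockUpdates
#' @param L filter matrix `n x n`.
#' @details `updateComponentTikhonov()` minimizes
#'   `||R - w a'||_F^2 + lam ||L w||^2 + tauW ||w - wPrev||^2` over
#'   `w >= 0` by [fnnls()] on the normal equations
#'   `G = ||a||^2 I + lam L'L + tauW I`, `f = R a + tauW wPrev`.
#'   With `L = I` this reduces to (and numerically reproduces) the
#'   closed-form shrinkage `max(0, f) / (||a||^2 + lam + tauW)`.
#' @export
updateComponentTikhonov <- function(R, a, wPrev, lam, L, tauW) {
  n <- nrow(R)
  if (length(wPrev) != n || ncol(R) != length(a))
    stop("dimension mismatch between R, a, wPrev")
  if (!all(dim(L) == c(n, n))) stop("'L' must be n x n")
  f <- drop(R %*% a) + tauW * wPrev
  G <- lam * crossprod(L)
  diag(G) <- diag(G) + sum(a^2) + tauW
  fnnls(G, f)
}

#' @rdname blockUpdates
#' @param X full data matrix `n x m`.
#' @param A full mixing matrix `m x k`.
#' @param WPrev previous component matrix `n x k`.
#' @param pairs two-column integer matrix of coupled component pairs.
#' @details `updateComponentRelated()` treats the whole of `W` as one
#'   block (the pair penalty couples columns, so per-column sweeps would
#'   not be exact) and minimizes
#'   `||X - W A'||_F^2 + lam ||W B||_F^2 + tauW ||W - WPrev||_F^2` over
#'   `W >= 0`, with `B` the signed pair-incidence matrix.  The problem
#'   decouples over the rows of `W`; each row solves [fnnls()] with the
#'   shared Gram `G = A'A + lam B B' + tauW I`, formed once per call.
#' @export
updateComponentRelated <- function(X, A, WPrev, lam, pairs, tauW) {
  k <- ncol(A)
  n <- nrow(X)
  if (!all(dim(WPrev) == c(n, k)) || nrow(A) != ncol(X))
    stop("dimension mismatch between X, A, WPrev")
  reg <- regRelated(lam, pairs)
  B <- pairIncidence(reg, k)
  G <- crossprod(A) + lam * tcrossprod(B)
  diag(G) <- diag(G) + tauW
  Fmat <- X %*% A + tauW * WPrev   # n x k; row i is the linear term f
  W <- matrix(0, n, k)
  for (i in seq_len(n)) W[i, ] <- fnnls(G, Fmat[i, ])
  W
}

#' @rdname blockUpdates
#' @param W component matrix `n x k`.
#' @details `refreshResidual()` recomputes `X - W A'` from scratch; the
#'   sweep maintains the residual cumulatively for speed and calls this
#'   periodically to bound floating-point drift.
#' @export
refreshResidual <- function(X, W, A) {
  X - W %*% t(A)
}
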