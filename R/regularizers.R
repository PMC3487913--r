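#' Regularizer constructors
#'
#' Build the [Regularizer-class] object passed to [regnmf()] and
#' [objectiveValue()].  All penalties act on the component matrix `W`
#' only; the mixing matrix is scale-locked instead of regularized.
#'
#' @param lam non-negative weight multiplying the penalty.
#' @return a [Regularizer-class] object.
#' @examples
#' regL1(0.5)
#' regTikhonov(1, differenceFilter(5, order = 1))
#' regRelated(2, pairs = cbind(1, 2))
#' @export
regNone <- function() {
  new("Regularizer", kind = "none", lam = 0,
      filter = matrix(0, 0, 0), pairs = emptyPairs())
}

#' @rdname regNone
#' @export
regL1 <- function(lam) {
  new("Regularizer", kind = "l1", lam = lam,
      filter = matrix(0, 0, 0), pairs = emptyPairs())
}

#' @rdname regNone
#' @param filter square numeric filter matrix `L` of size `n x n`
#'   (`n` = number of features); the penalty is `lam * ||L W||_F^2`.
#' @export
regTikhonov <- function(lam, filter) {
  new("Regularizer", kind = "tikhonov", lam = lam,
      filter = as.matrix(filter), pairs = emptyPairs())
}

#' @rdname regNone
#' @param pairs two-column matrix (or list of length-2 vectors) of
#'   component index pairs `(i, j)`, `i != j`; the penalty is
#'   `lam * sum ||w_i - w_j||^2` over the pairs.
#' @export
regRelated <- function(lam, pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  new("Regularizer", kind = "related", lam = lam,
      filter = matrix(0, 0, 0), pairs = pairs)
}

emptyPairs <- function() matrix(integer(), 0L, 2L)

#' Difference filter matrices for Tikhonov smoothing
#'
#' Convenience constructors for the filter `L` of [regTikhonov()]:
#' the identity (plain ridge shrinkage) or first/second-order difference
#' operators that penalize roughness along the feature axis.
#'
#' @param n number of features (rows of `W`).
#' @param order 0 for the identity, 1 for first differences
#'   (`(n-1) x n`, rows `w[i+1] - w[i]` — rectangular filters are padded
#'   with zero rows to `n x n`), 2 for second differences.
#' @return an `n x n` numeric matrix.
#' @export
differenceFilter <- function(n, order = 1) {
  stopifnot(n >= 1, order %in% 0:2)
  if (order == 0 || n <= order) return(diag(n))
  D <- diag(n)
  for (i in seq_len(order)) D <- diff(D)
  rbind(D, matrix(0, n - nrow(D), n))
}

## lam * dJ/dW for the supported penalties; used by the KKT diagnostics.
regGradient <- function(W, reg) {
  switch(reg@kind,
    none = matrix(0, nrow(W), ncol(W)),
    l1 = matrix(reg@lam, nrow(W), ncol(W)),
    tikhonov = 2 * reg@lam * crossprod(reg@filter) %*% W,
    related = 2 * reg@lam * W %*% tcrossprod(pairIncidence(reg, ncol(W))))
}

## Penalty value J(W) (unweighted).
regPenalty <- function(W, reg) {
  switch(reg@kind,
    none = 0,
    l1 = sum(W),
    tikhonov = sum((reg@filter %*% W)^2),
    related = sum((W %*% pairIncidence(reg, ncol(W)))^2))
}

## k x npairs signed incidence matrix B: column p has +1 at i_p, -1 at j_p.
pairIncidence <- function(reg, k) {
  p <- reg@pairs
  if (any(p > k)) stop("pair indices exceed the number of components")
  B <- matrix(0, k, nrow(p))
  for (q in seq_len(nrow(p))) {
    B[p[q, 1L], q] <- 1
    B[p[q, 2L], q] <- -1
  }
  B
}
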