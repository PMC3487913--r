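#' @import methods
NULL

#' Factor model for non-negative matrix factorization with exact scale control
#'
#' An `NMFModel` holds a rank-`k` non-negative factorization of an
#' `n x m` expression matrix as `X ~ W %*% t(A)`.  `W` (`n x k`) is the
#' component matrix whose columns are base vectors over features; `A`
#' (`m x k`) is the mixing matrix whose column `l` holds component `l`'s
#' coefficients across the `m` samples.  Each column of `A` lies on the
#' alpha-simplex: non-negative with coordinates summing to `alpha`
#' exactly, which locks the scale of the factorization.
#'
#' @slot W non-negative numeric matrix, features x components.
#' @slot A non-negative numeric matrix, samples x components; every column
#'   sums to `alpha` (to within `1e-9 * alpha` accumulated rounding).
#' @slot alpha positive scalar, the simplex scale.
#'
#' @seealso [regnmf()] which returns the [NMFFit-class] subclass,
#'   [basisMatrix()], [mixingMatrix()], [scaleAlpha()].
#' @export
setClass("NMFModel",
  representation(W = "matrix", A = "matrix", alpha = "numeric"))

setValidity("NMFModel", function(object) {
  msg <- character()
  W <- object@W; A <- object@A; alpha <- object@alpha
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    msg <- c(msg, "'alpha' must be a single positive finite number")
  if (!is.numeric(W) || !is.numeric(A))
    msg <- c(msg, "'W' and 'A' must be numeric matrices")
  else {
    if (ncol(W) != ncol(A))
      msg <- c(msg, "'W' and 'A' must have the same number of columns (k)")
    if (any(W < 0)) msg <- c(msg, "'W' has negative entries")
    if (any(A < 0)) msg <- c(msg, "'A' has negative entries")
    if (length(alpha) == 1L && is.finite(alpha) && alpha > 0 &&
        ncol(A) > 0) {
      dev <- max(abs(colSums(A) - alpha))
      if (dev > 1e-9 * alpha)
        msg <- c(msg, sprintf(
          "columns of 'A' must sum to alpha = %g (max deviation %g)",
          alpha, dev))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Fitted regularized NMF model with convergence trace
#'
#' Subclass of [NMFModel-class] returned by [regnmf()].  Adds the
#' per-sweep trace (objective, KKT residuals for both factors, sparsity of
#' `W`) and the convergence flags.
#'
#' @slot objective numeric vector, objective value after each sweep
#'   (non-increasing).
#' @slot kktW,kktA numeric vectors, per-sweep first-order residuals for the
#'   component and mixing factors.
#' @slot sparsityW numeric vector in `[0,1]`, fraction of exact zeros in
#'   `W` after each sweep.
#' @slot converged logical; `TRUE` only when the relative objective
#'   decrease fell below `tol` *and* both KKT residuals dropped below
#'   `1e-3` times their initial values (stricter than the objective rule
#'   alone; the trace keeps both recoverable).
#' @slot objConverged logical; the plain relative-objective-decrease
#'   stopping rule on its own.
#' @slot sweeps integer, number of sweeps performed.
#' @slot regularizer the [Regularizer-class] used.
#' @slot control list of solver settings (see [rnmfControl()]).
#' @export
setClass("NMFFit",
  contains = "NMFModel",
  representation(
    objective = "numeric", kktW = "numeric", kktA = "numeric",
    sparsityW = "numeric", converged = "logical",
    objConverged = "logical", sweeps = "integer",
    regularizer = "ANY", control = "list"))

#' Regularization term on the component matrix
#'
#' Describes the penalty `J(W)` added to the reconstruction loss, scaled
#' by a non-negative weight `lam`:
#' \describe{
#'   \item{none}{`J = 0`.}
#'   \item{l1}{`J = sum(W)` (entries are non-negative, so this is the
#'     entrywise l1 norm); promotes exact zeros in `W`.}
#'   \item{tikhonov}{`J = ||L W||_F^2` for an `n x n` filter matrix `L`
#'     (identity for plain ridge, difference operators for smoothing).}
#'   \item{related}{`J = sum over pairs (i,j) of ||w_i - w_j||^2`,
#'     pulling designated pairs of base vectors together.}
#' }
#'
#' @slot kind one of `"none"`, `"l1"`, `"tikhonov"`, `"related"`.
#' @slot lam non-negative regularization weight.
#' @slot filter the filter matrix `L` (tikhonov only), else a 0x0 matrix.
#' @slot pairs integer matrix with two columns, one row per coupled pair
#'   (related only), else 0x2.
#'
#' @seealso [regNone()], [regL1()], [regTikhonov()], [regRelated()]
#' @export
setClass("Regularizer",
  representation(kind = "character", lam = "numeric",
                 filter = "matrix", pairs = "matrix"))

setValidity("Regularizer", function(object) {
  msg <- character()
  if (!object@kind %in% c("none", "l1", "tikhonov", "related"))
    msg <- c(msg, "kind must be one of none/l1/tikhonov/related")
  if (length(object@lam) != 1L || !is.finite(object@lam) || object@lam < 0)
    msg <- c(msg, "'lam' must be a single non-negative finite number")
  if (object@kind == "tikhonov") {
    L <- object@filter
    if (nrow(L) == 0L || ncol(L) != nrow(L) || !all(is.finite(L)))
      msg <- c(msg, "tikhonov regularizer needs a finite square filter matrix")
  }
  if (object@kind == "related") {
    p <- object@pairs
    if (nrow(p) == 0L)
      msg <- c(msg, "related regularizer needs a non-empty pair list")
    else if (any(p < 1L) || any(p[, 1L] == p[, 2L]))
      msg <- c(msg, "pairs must hold distinct positive indices")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn NMFModel-class construct a model from its two factors.
#' @param W,A,alpha see slots.
#' @export
NMFModel <- function(W, A, alpha = 1) {
  new("NMFModel", W = as.matrix(W), A = as.matrix(A), alpha = alpha)
}

#' Accessors for NMF factor models
#'
#' `basisMatrix()` returns the component matrix `W` (features x
#' components), `mixingMatrix()` the mixing matrix `A` (samples x
#' components) and `scaleAlpha()` the simplex scale `alpha`.
#' `fitted()` returns the reconstruction `W %*% t(A)`.
#'
#' @param object an [NMFModel-class] or [NMFFit-class].
#' @return the requested slot (a matrix or scalar).
#' @aliases basisMatrix mixingMatrix scaleAlpha
#' @export
setGeneric("basisMatrix", function(object) standardGeneric("basisMatrix"))

#' @rdname basisMatrix
#' @export
setGeneric("mixingMatrix", function(object) standardGeneric("mixingMatrix"))

#' @rdname basisMatrix
#' @export
setGeneric("scaleAlpha", function(object) standardGeneric("scaleAlpha"))

#' @rdname basisMatrix
#' @export
setMethod("basisMatrix", "NMFModel", function(object) object@W)

#' @rdname basisMatrix
#' @export
setMethod("mixingMatrix", "NMFModel", function(object) object@A)

#' @rdname basisMatrix
#' @export
setMethod("scaleAlpha", "NMFModel", function(object) object@alpha)

#' @rdname basisMatrix
#' @param ... ignored.
#' @export
setMethod("fitted", "NMFModel",
  function(object, ...) object@W %*% t(object@A))

#' Per-sweep convergence trace of a fit
#'
#' @param object an [NMFFit-class].
#' @return a `data.frame` with one row per sweep and columns `sweep`,
#'   `objective`, `kktW`, `kktA`, `sparsityW`.
#' @export
setGeneric("fitTrace", function(object) standardGeneric("fitTrace"))

#' @rdname fitTrace
#' @export
setMethod("fitTrace", "NMFFit", function(object) {
  data.frame(sweep = seq_len(object@sweeps),
             objective = object@objective,
             kktW = object@kktW, kktA = object@kktA,
             sparsityW = object@sparsityW)
})

setMethod("show", "NMFModel", function(object) {
  cat(sprintf("%s: %d features x %d samples, k = %d components, alpha = %g\n",
              class(object), nrow(object@W), nrow(object@A),
              ncol(object@W), object@alpha))
})

setMethod("show", "NMFFit", function(object) {
  callNextMethod()
  ns <- object@sweeps
  cat(sprintf("  regularizer: %s (lam = %g)\n",
              object@regularizer@kind, object@regularizer@lam))
  cat(sprintf("  %d sweeps; objective %.6g; kktW %.3g; kktA %.3g; sparsity(W) %.1f%%\n",
              ns, object@objective[ns], object@kktW[ns], object@kktA[ns],
              100 * object@sparsityW[ns]))
  cat(sprintf("  converged: %s (objective rule: %s)\n",
              object@converged, object@objConverged))
})

setMethod("show", "Regularizer", function(object) {
  cat(sprintf("Regularizer: %s, lam = %g", object@kind, object@lam))
  if (object@kind == "tikhonov")
    cat(sprintf(", filter %dx%d", nrow(object@filter), ncol(object@filter)))
  if (object@kind == "related")
    cat(sprintf(", %d pair(s)", nrow(object@pairs)))
  cat("\n")
})
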