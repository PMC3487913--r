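#' Fast non-negative least squares on normal equations
#'
#' Solves `argmin_{x >= 0} 0.5 * x' G x - f' x` for a symmetric positive
#' definite Gram matrix `G`, by the Lawson-Hanson active-set strategy
#' rewritten to operate directly on the normal equations (the Bro-de Jong
#' FNNLS formulation): the stacked least-squares design never has to be
#' formed, which is what makes the Tikhonov and related-base-vector
#' component updates cheap.
#'
#' The passive set grows by the coordinate with the most positive dual
#' residual `w = f - G x`; whenever the unconstrained solve on the
#' passive set turns a coordinate non-positive, the iterate steps to the
#' boundary along the smallest feasible ratio (ties to the lowest index,
#' the standard anti-cycling rule) and that coordinate leaves the set.
#' Returns with a KKT certificate: `x >= 0`, dual residuals `<=`
#' tolerance on the active set, complementary slackness on the passive
#' set.
#'
#' @param G symmetric positive definite `d x d` matrix.  Callers inside
#'   the solver guarantee positive definiteness through the proximal
#'   term.
#' @param f numeric vector of length `d`.
#' @param tol dual-feasibility tolerance; default `1e-10 * (1 + max(abs(f)))`
#'   (scale-aware).
#' @return non-negative numeric vector of length `d`.
#' @examples
#' fnnls(diag(2), c(-1, 2))   # clips the negative coordinate: (0, 2)
#' @export
fnnls <- function(G, f, tol = NULL) {
  d <- length(f)
  G <- as.matrix(G)
  if (!isTRUE(all.equal(dim(G), c(d, d))))
    stop("'G' must be square and conform with 'f'")
  if (max(abs(G - t(G))) > 1e-10 * max(1, max(abs(G))))
    stop("'G' must be symmetric")
  if (is.null(tol)) tol <- 1e-10 * (1 + max(abs(f)))

  x <- numeric(d)
  passive <- rep(FALSE, d)
  w <- f                      # dual residual f - G x at x = 0
  iter <- 0L; maxIter <- 30L * d

  repeat {
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > maxIter)
        stop("fnnls: iteration limit exceeded (ill-conditioned system?)")
      P <- which(passive)
      z <- numeric(d)
      sol <- tryCatch(solve(G[P, P, drop = FALSE], f[P]),
                      error = function(e) NULL)
      if (is.null(sol))
        stop("fnnls: restricted system not positive definite ",
             "(is the proximal term missing?)")
      z[P] <- sol
      if (all(z[P] > 0)) { x <- z; break }
      # step toward z until the first passive coordinate hits zero
      hit <- P[z[P] <= 0]
      ratio <- x[hit] / (x[hit] - z[hit])
      stepLen <- min(ratio)
      x <- x + stepLen * (z - x)
      drop <- hit[which(ratio <= stepLen + 1e-15)]  # lowest index on ties
      passive[drop[1L]] <- FALSE
      x[!passive] <- 0
    }
    w <- f - drop(G %*% x)
  }
  x
}
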