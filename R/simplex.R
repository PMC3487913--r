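#' Euclidean projection onto the alpha-simplex
#'
#' Returns the unique minimizer of `0.5 * ||h - c||^2` over the
#' alpha-simplex (non-negative vectors summing to `alpha`).  This is the
#' exact solver for every mixing-column block of the factorization: after
#' rank-one reduction each block objective is a diagonal quadratic, so its
#' constrained minimum is the projection of an explicit point.
#'
#' The algorithm sorts `c` in descending order, computes the running
#' multiplier `mu_q = (sum of the q largest entries - alpha) / q` and
#' selects the largest support size `q*` with `c_(q*) - mu_{q*} > 0`; the
#' output is `pmax(c - mu_{q*}, 0)`.  Beyond the sort this is a single
#' linear pass.  At the solution all partial derivatives `h_i - c_i` at
#' non-zero coordinates equal the smallest partial derivative, the
#' first-order optimality condition on the simplex.
#'
#' @param c numeric vector (entries may be negative).
#' @param alpha positive scale of the simplex.
#' @return numeric vector of `length(c)`: non-negative, summing to
#'   `alpha` exactly.
#' @examples
#' projectSimplex(c(0.5, 0.2, -0.1), 1)   # interior support, q* = 3
#' projectSimplex(c(10, 0, 0), 1)         # single dominant coordinate
#' @export
projectSimplex <- function(c, alpha) {
  if (!is.numeric(c) || length(c) < 1L || !all(is.finite(c)))
    stop("'c' must be a finite numeric vector")
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  d <- length(c)
  cs <- sort(c, decreasing = TRUE, method = "radix")
  mu <- (cumsum(cs) - alpha) / seq_len(d)
  qstar <- max(which(cs - mu > 0))
  h <- pmax(c - mu[qstar], 0)
  # pin the column sum to alpha exactly (redistribute rounding over support)
  s <- sum(h)
  if (s != alpha) {
    pos <- h > 0
    h[pos] <- h[pos] * (alpha / s)
  }
  h
}

#' First-order optimality gap on the alpha-simplex
#'
#' For a feasible point `h` and the gradient `grad` of a convex block
#' objective at `h`, the point is optimal iff every partial derivative at
#' a non-zero coordinate equals the smallest partial derivative.  The gap
#' reported is `max over {i : h_i > 0} of (grad_i - min_j grad_j)`; it is
#' zero (to tolerance) exactly at a constrained minimum.
#'
#' @param grad numeric gradient vector.
#' @param h feasible point on the simplex, same length.
#' @return non-negative scalar.
#' @export
simplexOptimalityGap <- function(grad, h) {
  if (length(grad) != length(h))
    stop("'grad' and 'h' must have the same length")
  active <- h > 0
  if (!any(active)) return(0)
  max(grad[active]) - min(grad)
}
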