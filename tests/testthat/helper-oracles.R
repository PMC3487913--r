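# Independent brute-force oracles used to pin the closed-form solvers.
# These deliberately avoid the package's own code paths.

# Exhaustive-support minimizer of 0.5*||h - c||^2 over the alpha-simplex:
# enumerate all 2^d - 1 supports, solve the equality-constrained problem
# on each, keep feasible candidates, return the best.
bruteSimplex <- function(c, alpha) {
  d <- length(c)
  best <- NULL; bestObj <- Inf
  for (mask in seq_len(2^d - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(d) - 1)) > 0)
    mu <- (sum(c[S]) - alpha) / length(S)
    h <- numeric(d); h[S] <- c[S] - mu
    if (all(h[S] >= -1e-12)) {
      obj <- 0.5 * sum((h - c)^2)
      if (obj < bestObj) { bestObj <- obj; best <- pmax(h, 0) }
    }
  }
  best
}

# Early-exit variant of the sorted linear search: stop at the first q with
# q = d or mu_q >= c_(q+1).  Must agree with the max-q selection rule.
earlyExitSimplex <- function(c, alpha) {
  d <- length(c)
  cs <- sort(c, decreasing = TRUE)
  csum <- 0
  for (q in seq_len(d)) {
    csum <- csum + cs[q]
    mu <- (csum - alpha) / q
    if (q == d || mu >= cs[q + 1]) break
  }
  pmax(c - mu, 0)
}

# Exhaustive active-set minimizer of 0.5*x'Gx - f'x over x >= 0: try all
# 2^d passive sets, solve the restricted system, keep candidates that are
# primal feasible and dual feasible, return the best objective.
bruteNNLS <- function(G, f) {
  d <- length(f)
  best <- NULL; bestObj <- Inf
  for (mask in 0:(2^d - 1)) {
    P <- which(bitwAnd(mask, 2^(seq_len(d) - 1)) > 0)
    x <- numeric(d)
    if (length(P)) {
      sol <- tryCatch(solve(G[P, P, drop = FALSE], f[P]),
                      error = function(e) NULL)
      if (is.null(sol) || any(sol < -1e-12)) next
      x[P] <- pmax(sol, 0)
    }
    grad <- drop(G %*% x) - f
    if (any(grad < -1e-8)) next
    obj <- 0.5 * sum(x * drop(G %*% x)) - sum(f * x)
    if (obj < bestObj) { bestObj <- obj; best <- x }
  }
  best
}

# random symmetric positive definite matrix
randomPD <- function(d) {
  M <- matrix(rnorm(d * d), d, d)
  crossprod(M) + diag(d) * 0.5
}

# scalar minimization by coarse grid + golden-section refinement;
# used as a per-coordinate oracle for the soft-threshold update
scalarMin <- function(fn, lo, hi, n = 2001L) {
  xs <- seq(lo, hi, length.out = n)
  x0 <- xs[which.min(vapply(xs, fn, numeric(1)))]
  stats::optimize(fn, c(max(lo, x0 - (hi - lo) / n * 2),
                        min(hi, x0 + (hi - lo) / n * 2)))$minimum
}

# feasible-direction finite-difference check: directional derivative of
# fn at x along d, forward difference with step t
fdDirDeriv <- function(fn, x, d, t = 1e-6) {
  (fn(x + t * d) - fn(x)) / t
}

# random feasible directions on the simplex at point a: zero-sum, and
# non-negative where a has a zero coordinate
simplexDirections <- function(a, nDir = 20L) {
  d <- length(a)
  out <- list()
  for (i in seq_len(nDir)) {
    v <- rnorm(d)
    v[a <= 0] <- abs(v[a <= 0])
    pos <- a > 0
    if (!any(pos)) next
    v[pos] <- v[pos] - sum(v) / sum(pos)  # restore zero sum on free coords
    if (any(v[a <= 0] < 0)) next
    out[[length(out) + 1L]] <- v / max(abs(v))
  }
  out
}
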