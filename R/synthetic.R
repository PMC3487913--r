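#' Simulate an expression matrix with planted factor structure
#'
#' Generates a ground-truth factor pair and a noisy non-negative data
#' matrix with the additive structure the factorization model assumes:
#' `X = max(0, W A' + noise)`.  Base-vector entries are `|Normal(0,1)|`
#' with a uniformly random set of exactly `round(plantedSparsity * n * k)`
#' entries forced to zero (redrawing, up to a bound, if a column comes
#' out all-zero); mixing columns are flat-Dirichlet over the samples,
#' scaled to `alpha`.  Truncated-Gaussian noise keeps the matrix
#' non-negative with a single dispersion parameter.  Deterministic given
#' `seed`.
#'
#' @param n,m,k features, samples, components (`k <= min(n, m)`).
#' @param alpha simplex scale of the true mixing columns.
#' @param plantedSparsity zero fraction planted in the true `W`, in
#'   `[0, 1)`.
#' @param noiseSd standard deviation of the additive Gaussian noise
#'   before truncation at zero.
#' @param seed integer seed.
#' @return a list with `X` (labeled `n x m` matrix), `WTrue`, `ATrue`,
#'   `alpha`, `plantedSparsity`, `noiseSd`, `seed`.
#' @examples
#' sim <- simulateExpression(60, 40, 4, plantedSparsity = 0.5, seed = 0)
#' sum(sim$WTrue == 0)  # exactly 120 planted zeros
#' @export
simulateExpression <- function(n, m, k, alpha = 1, plantedSparsity = 0,
                               noiseSd = 0, seed = NULL) {
  stopifnot(n >= 1, m >= 1, k >= 1, k <= min(n, m),
            plantedSparsity >= 0, plantedSparsity < 1, noiseSd >= 0)
  nZero <- round(plantedSparsity * n * k)
  withSeed(seed, {
    W <- NULL
    for (try in seq_len(100L)) {
      Wcand <- matrix(abs(stats::rnorm(n * k)), n, k)
      if (nZero > 0)
        Wcand[sample.int(n * k, nZero)] <- 0
      if (all(colSums(Wcand) > 0)) { W <- Wcand; break }
    }
    if (is.null(W))
      stop("infeasible sparsity: a component column came out all-zero")
    # flat Dirichlet over samples via normalized Exp(1) draws
    A <- matrix(stats::rgamma(m * k, shape = 1), m, k)
    A <- sweep(A, 2L, colSums(A) / alpha, "/")
    X <- W %*% t(A)
    if (noiseSd > 0)
      X <- pmax(X + matrix(stats::rnorm(n * m, sd = noiseSd), n, m), 0)
    dimnames(X) <- list(paste0("gene_", seq_len(n)),
                        paste0("sample_", seq_len(m)))
    list(X = X, WTrue = W, ATrue = A, alpha = alpha,
         plantedSparsity = plantedSparsity, noiseSd = noiseSd, seed = seed)
  })
}

#' Match fitted components to ground truth
#'
#' NMF is identifiable only up to permutation (and, absent scale locking,
#' rescaling) of the components, so fitted and true base vectors must be
#' aligned before comparison.  Components are paired greedily on the
#' `k x k` matrix of cosine similarities between columns: the globally
#' largest entry is matched first, its row and column removed, and so on.
#' A zero column has cosine 0 against everything.
#'
#' @param WFit,WTrue matrices of identical dimensions whose columns are
#'   fitted and true base vectors.
#' @return list with `permutation` (`permutation[l]` is the index of the
#'   true component matched to fitted component `l`) and `cosine`
#'   (similarity of each matched pair, indexed by fitted component).
#' @export
matchComponents <- function(WFit, WTrue) {
  stopifnot(all(dim(WFit) == dim(WTrue)))
  k <- ncol(WFit)
  nf <- sqrt(colSums(WFit^2)); nt <- sqrt(colSums(WTrue^2))
  C <- crossprod(WFit, WTrue)
  scale <- outer(nf, nt)
  C <- ifelse(scale > 0, C / scale, 0)
  perm <- integer(k); sim <- numeric(k)
  rows <- seq_len(k); cols <- seq_len(k)
  Cw <- C
  for (step in seq_len(k)) {
    ij <- which(Cw == max(Cw), arr.ind = TRUE)[1L, ]
    i <- rows[ij[1L]]; j <- cols[ij[2L]]
    perm[i] <- j; sim[i] <- C[i, j]
    Cw <- Cw[-ij[1L], -ij[2L], drop = FALSE]
    rows <- rows[-ij[1L]]; cols <- cols[-ij[2L]]
  }
  list(permutation = perm, cosine = sim)
}
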