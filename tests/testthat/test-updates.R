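test_that("mixing-column update recovers exact rank-one structure and degenerate safeguards", {
  set.seed(3)
  w <- runif(4); aStar <- projectSimplex(runif(3), 1)
  R <- tcrossprod(w, aStar)
  # tiny proximal weight: unconstrained optimum already feasible
  out <- updateMixingColumn(R, w, rep(1 / 3, 3), 1, 1e-12)
  expect_equal(out, aStar, tolerance = 1e-8)
  # degenerate base vector: proximal term hands back the previous point
  aPrev <- projectSimplex(runif(3), 1)
  expect_equal(updateMixingColumn(R, numeric(4), aPrev, 1, 0.5), aPrev,
               tolerance = 1e-12)
  expect_error(updateMixingColumn(R, w, aPrev, 1, 0), "positive")
})

test_that("mixing-column update equals the simplex oracle on the worked fixture", {
  R <- rbind(c(1, 0, 2), c(0, 1, 0))
  w <- c(1, 1)
  out <- updateMixingColumn(R, w, rep(1 / 3, 3), 1, 0.1)
  # c = (R'w + 0.1 * aPrev) / 2.1 = (31, 31, 61)/63; projection keeps full
  # support with mu = 20/63
  expect_equal(out, c(11, 11, 41) / 63, tolerance = 1e-12)
  cvec <- (drop(crossprod(R, w)) + 0.1 / 3) / 2.1
  expect_equal(out, bruteSimplex(cvec, 1), tolerance = 1e-12)
})

test_that("l1 component update soft-thresholds exactly", {
  set.seed(4)
  # unregularized exact rank-one data is recovered
  wStar <- c(0.2, 0, 1.5); a <- runif(4)
  R <- tcrossprod(wStar, a)
  expect_equal(updateComponentL1(R, a, numeric(3), 0, 0), wStar,
               tolerance = 1e-12)
  # full shrinkage at lam >= 2 max (R a)
  lamBig <- 2 * max(R %*% a) + 0.1
  expect_equal(updateComponentL1(R, a, numeric(3), lamBig, 0), numeric(3))
  expect_error(updateComponentL1(R, numeric(4), numeric(3), 1, 0),
               "strictly convex")
})

test_that("each l1 coordinate matches a scalar grid+refinement oracle", {
  R <- rbind(c(0.8, 0.1, 0.4), c(0.05, 0.02, 0.01), c(1.2, 0.9, 1.1))
  a <- c(1, 0.5, sqrt(2 - 1.25))   # ||a||^2 = 2
  lam <- 1
  w <- updateComponentL1(R, a, numeric(3), lam, 0)
  expect_equal(w, pmax(0, drop(R %*% a) - 0.5) / 2, tolerance = 1e-12)
  for (i in 1:3) {
    fn <- function(wi) sum((R[i, ] - wi * a)^2) + lam * wi
    expect_equal(w[i], max(0, scalarMin(fn, 0, 2)), tolerance = 1e-4)
  }
})

test_that("l1 solutions shrink coordinatewise as lam grows", {
  set.seed(5)
  R <- matrix(runif(15), 3, 5); a <- runif(5)
  lams <- c(0, 0.2, 0.5, 1, 2, 5)
  ws <- sapply(lams, function(l) updateComponentL1(R, a, numeric(3), l, 0))
  for (j in seq_len(ncol(ws) - 1)) {
    expect_true(all(ws[, j + 1] <= ws[, j] + 1e-12))
    expect_gte(sum(ws[, j + 1] == 0), sum(ws[, j] == 0))
  }
})

test_that("tikhonov update reduces to l1 at lam 0 and to closed-form shrinkage at L = I", {
  set.seed(6)
  R <- matrix(runif(12), 4, 3); a <- runif(3); wPrev <- runif(4)
  expect_equal(updateComponentTikhonov(R, a, wPrev, 0, diag(4), 1e-3),
               updateComponentL1(R, a, wPrev, 0, 1e-3), tolerance = 1e-10)
  for (rep in 1:10) {
    R <- matrix(rnorm(12, 1), 4, 3); a <- runif(3); wPrev <- runif(4)
    lam <- runif(1, 0, 2); tau <- runif(1, 0, 0.1)
    f <- drop(R %*% a) + tau * wPrev
    expect_equal(updateComponentTikhonov(R, a, wPrev, lam, diag(4), tau),
                 pmax(0, f) / (sum(a^2) + lam + tau), tolerance = 1e-10)
  }
})

test_that("tikhonov update with a difference filter matches the exhaustive oracle", {
  set.seed(7)
  L <- differenceFilter(5, 1)
  for (rep in 1:20) {
    R <- matrix(rnorm(15), 5, 3); a <- runif(3); wPrev <- runif(5)
    w <- updateComponentTikhonov(R, a, wPrev, 1, L, 1e-6)
    G <- sum(a^2) * diag(5) + crossprod(L) + 1e-6 * diag(5)
    f <- drop(R %*% a) + 1e-6 * wPrev
    expect_lt(max(abs(w - bruteNNLS(G, f))), 1e-8)
  }
})

test_that("related update solves row-decoupled NNLS and merges paired columns in the stiff limit", {
  set.seed(8)
  # lam = 0: plain per-row NNLS of the reconstruction
  for (rep in 1:10) {
    n <- 3; m <- 5; k <- 3
    X <- matrix(abs(rnorm(n * m)), n, m)
    A <- apply(matrix(runif(m * k), m, k), 2, function(x) x / sum(x))
    W <- updateComponentRelated(X, A, matrix(0, n, k), 0, rbind(c(1, 2)), 0)
    G <- crossprod(A)
    for (i in seq_len(n))
      expect_lt(max(abs(W[i, ] - bruteNNLS(G, drop(X[i, ] %*% A)))), 1e-8)
  }
  # stiff pair penalty forces the paired columns together
  X <- matrix(abs(rnorm(8 * 6)), 8, 6)
  A <- apply(matrix(runif(6 * 3), 6, 3), 2, function(x) x / sum(x))
  W <- updateComponentRelated(X, A, matrix(1, 8, 3), 1e8, rbind(c(1, 2)), 1e-6)
  expect_lt(sqrt(sum((W[, 1] - W[, 2])^2)) / max(sqrt(sum(W[, 1]^2)), 1e-12),
            1e-3)
})

test_that("related update agrees with a two-variable grid oracle on a micro fixture", {
  # n = 1, m = 2, k = 2: minimize (over w >= 0)
  #   sum_j (X[1,j] - w1 A[j,1] - w2 A[j,2])^2 + lam (w1 - w2)^2
  X <- matrix(c(1.0, 0.4), 1, 2)
  A <- rbind(c(0.7, 0.2), c(0.3, 0.8))
  lam <- 0.3
  W <- updateComponentRelated(X, A, matrix(0, 1, 2), lam, rbind(c(1, 2)), 0)
  obj <- function(w) sum((X[1, ] - drop(A %*% w))^2) + lam * (w[1] - w[2])^2
  grid <- seq(0, 2, length.out = 401)
  vals <- outer(grid, grid, Vectorize(function(u, v) obj(c(u, v))))
  idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  coarse <- c(grid[idx[1]], grid[idx[2]])
  ref <- stats::optim(coarse, obj, lower = c(0, 0), method = "L-BFGS-B")$par
  expect_equal(drop(W), ref, tolerance = 1e-5)
  expect_error(updateComponentRelated(X, A, matrix(0, 1, 2), 1,
                                      rbind(c(1, 5)), 0), "exceed")
})

test_that("cumulative residual bookkeeping stays within drift bounds", {
  set.seed(9)
  sim <- simulateExpression(20, 15, 3, plantedSparsity = 0.3, noiseSd = 0.1,
                            seed = 9)
  X <- sim$X
  model <- initFactors(X, 3, 1, seed = 1)
  W <- basisMatrix(model); A <- mixingMatrix(model)
  expect_equal(refreshResidual(X, 0 * W, A), X)
  R <- refreshResidual(X, W, A)
  # 50 manual cumulative sweeps without any refresh
  for (s in 1:50) {
    for (l in 1:3) {
      R <- R + tcrossprod(W[, l], A[, l])
      W[, l] <- updateComponentL1(R, A[, l], W[, l], 0.05, 1e-6)
      A[, l] <- updateMixingColumn(R, W[, l], A[, l], 1, 1e-6)
      R <- R - tcrossprod(W[, l], A[, l])
    }
  }
  fresh <- refreshResidual(X, W, A)
  expect_lt(sqrt(sum((R - fresh)^2)) / sqrt(sum(X^2)), 1e-6)
})

test_that("every exact block update is monotone for the global objective", {
  set.seed(10)
  for (rep in 1:10) {
    n <- 6; m <- 5; k <- 3
    X <- matrix(abs(rnorm(n * m)), n, m)
    model <- initFactors(X, k, 1, seed = rep)
    W <- basisMatrix(model); A <- mixingMatrix(model)
    reg <- regL1(0.1)
    Fbefore <- objectiveValue(X, NMFModel(W, A, 1), reg)
    l <- sample(k, 1)
    R <- X - W %*% t(A) + tcrossprod(W[, l], A[, l])
    W[, l] <- updateComponentL1(R, A[, l], W[, l], reg@lam, 1e-8)
    Fmid <- objectiveValue(X, NMFModel(W, A, 1), reg)
    expect_lte(Fmid, Fbefore + 1e-10 * max(1, Fbefore))
    A[, l] <- updateMixingColumn(R, W[, l], A[, l], 1, 1e-8)
    Fafter <- objectiveValue(X, NMFModel(W, A, 1), reg)
    expect_lte(Fafter, Fmid + 1e-10 * max(1, Fmid))
    # the refreshed mixing column is block-optimal for its subproblem
    grad <- 2 * (sum(W[, l]^2) * A[, l] - drop(crossprod(R, W[, l])))
    expect_lt(simplexOptimalityGap(grad, A[, l]), 1e-6)
  }
})
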