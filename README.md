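# regnmf — regularized NMF with exact scale control

`regnmf` decomposes non-negative gene expression matrices (bulk or
single-cell, features × samples) as `X ≈ W Aᵀ`, where the columns of the
component matrix `W` are non-negative expression programs and each row
of a sample's mixing coefficients says how much of each program it
contains.  It is aimed at analysts who want *regularized* NMF — sparse
components, smoothed components, or components tied to each other —
without the numerical pathologies that regularization usually brings.

## The problem and the method

NMF solves `min ||X − W Aᵀ||²_F` over non-negative factors.  Adding a
scale-dependent penalty `λ J(W)` (ℓ1 for sparsity, `||L W||²_F` for
smoothness, pairwise distances for related components) breaks the naive
formulation: the optimizer can shrink `W` toward zero and inflate `A`
without changing the fit, gaming the penalty.  `regnmf` therefore solves

```
min  ||X − W Aᵀ||²_F + λ J(W)    s.t.  W ≥ 0,  A ≥ 0,  1ᵀa_l = α  for every column a_l of A
```

— every mixing column is held on the α-simplex, locking the scale of the
unregularized factor *exactly*.  The solver is block-coordinate descent
in which every block subproblem is minimized exactly (a sorted
linear-search Euclidean projection onto the simplex for mixing columns;
closed-form soft-thresholding or active-set non-negative least squares
on normal equations for component columns) with a proximal-point
safeguard that keeps each subproblem strictly convex.  Consequences the
package tests mechanically:

* the objective trace is non-increasing, sweep by sweep;
* column sums of `A` equal α to within 1e-9·α at all times;
* limit points satisfy the first-order (KKT) conditions, and the
  per-sweep KKT residuals for both factors are part of the returned
  trace (`fitTrace()`), so "converged" is a measurable statement.

A bisection search (`lambdaForSparsity()`) selects the ℓ1 weight that
yields a requested fraction of exact zeros in `W`, which is how sparse
expression decompositions are usually specified in practice.

## Worked example

```r
library(regnmf)

# synthetic instance with planted structure: 60 genes x 40 samples,
# 4 components, half the true loadings exactly zero, mild noise
sim <- simulateExpression(60, 40, 4, alpha = 1, plantedSparsity = 0.5,
                          noiseSd = 0.05, seed = 0)

# choose the l1 weight that makes half of W exactly zero, then inspect
res <- lambdaForSparsity(sim$X, k = 4, target = 0.5, seed = 0)
res$fit
#> NMFFit: 60 features x 40 samples, k = 4 components, alpha = 1
#>   regularizer: l1 (lam = 0.0691255)
#>   41 sweeps; objective 8.71508; kktW 0.000984; kktA 0.0228; sparsity(W) 50.8%
#>   converged: FALSE (objective rule: TRUE)

matchComponents(basisMatrix(res$fit), sim$WTrue)$cosine
#> [1] 0.9210 0.8507 0.9541 0.9051
```

The fit stopped on the relative objective-decrease rule (`tol = 1e-5`)
with 50.8% of `W` exactly zero — within two points of the requested 50%.
`converged: FALSE` reports the stricter KKT-based flag: at this loose
tolerance the residuals have not yet dropped three orders of magnitude
(run with `rnmfControl(tol = 1e-8)` and they do).  The matched cosine
similarities show each fitted component aligned with one planted
program; at `noiseSd = 0` and tighter tolerance they exceed 0.95.

Factors, trace and configuration can be written to and re-read from a
directory with `writeModel()` / `readModel()` (TSV + JSON, components
ordered by strength).

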