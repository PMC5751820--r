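# robimc — robust inductive matrix completion for association prediction

Catalogues of links between two entity sets — the motivating case is long
intergenic non-coding RNAs (lincRNAs) versus human disease phenotypes — are
sparse binary matrices in which a 0 means *untested*, not *absent*.
Classical matrix-factorization recommenders cannot say anything about an
entity with no observed links. Inductive matrix completion (IMC) fixes the
cold-start problem by modelling every cell through side-information
features of both entities:

    A[i, j] ≈ xᵢ' Z yⱼ,   Z = W H',   W ≥ 0, H ≥ 0, rank(Z) ≤ r,

with `X` (M×m) holding row-entity features and `Y` (N×n) column-entity
features. A new entity only needs a feature vector to be scored.

`robimc` implements three solvers for this model plus the full evaluation
machinery around them:

* **`fit_imc()`** — standard IMC: squared Frobenius loss with ridge
  penalties, minimized by KKT-derived multiplicative updates.
* **`fit_rimc()`** — robust IMC: every norm replaced by the row-wise
  l2,1 norm `Σᵢ ‖Mᵢ·‖₂`, so corrupted rows contribute linearly instead of
  quadratically; minimized by iteratively reweighted multiplicative
  updates (diagonal weights `D = 1/‖residual row‖`, `P = 1/‖W row‖`,
  `Q = 1/‖H row‖`) with a monotone objective trace and a scaled KKT
  complementarity residual as convergence diagnostic.
* **`fit_srimc()`** — stable robust IMC, a two-step strategy: recover
  `Ẑ = (X'X)⁻¹ X'AY (Y'Y)⁻¹` in closed form from the feature-space normal
  equations (`solve_Z()`, linear solves with an optional ridge and
  rank-deficiency flags), clamp at zero, then factorize `Ẑ ≈ WH'` by
  robust l2,1 NMF (`fit_robust_nmf()`).

Around the solvers: precision@k / recall@k ranking evaluation with
cross-validation and three cold-start hold-out designs
(`run_benchmark()`, `make_cv_folds()`, `holdout_new_rows()`,
`holdout_new_cols()`, `holdout_both()`); a seeded synthetic benchmark
generator with planted low-rank structure and outlier-row injection
(`generate_planted_dataset()`, `inject_outlier_rows()`); truncated-SVD
feature compression (`reduce_features_svd()`); Matrix Market / TSV
readers and writers; and a CLI (`run_cli()`, `inst/exec/robimc`) with
`simulate`, `fit`, `predict` and `evaluate` subcommands.

## Worked example

Simulate a 100×250 association benchmark with planted rank-5 structure,
then compare the three solvers on cold-start prediction for 10% held-out
row entities:

```r
library(robimc)
ds  <- generate_planted_dataset(list(seed = 1))
cfg <- train_config(rank = 5, lambda1 = 0.01, lambda2 = 0.01,
                    max_iter = 300, tol = 1e-6, seed = 1)

fit <- fit_srimc(ds$A, ds$X, ds$Y, cfg)
fit
#> <srimc fit> rank 5, 300 iterations (max_iter reached), objective 0.0724941, KKT residual 0.00303

run_benchmark(c("imc", "rimc", "srimc"), ds, mode = "new_rows",
              k_grid = c(10L, 25L), n_repeats = 5L, seed = 1, config = cfg)
#>    method     mode  k    metric  mean      sd n_repeats
#> 1     imc new_rows 10 precision 0.296 0.00548         5
#> 2    rimc new_rows 10 precision 0.296 0.00548         5
#> 3   srimc new_rows 10 precision 0.732 0.02387         5
#> ...
#> 10    imc new_rows 25    recall 0.706 0.04261         5
#> 11   rimc new_rows 25    recall 0.725 0.02792         5
#> 12  srimc new_rows 25    recall 0.872 0.05402         5
```

Each row is the mean (± sd over 5 hold-out repeats) of a ranking metric:
for every held row entity — whose links were removed from training
entirely, so it is scored purely from its features — the columns are
ranked by predicted score and precision@k / recall@k count how many of its
hidden true links appear in the top k. The random-guessing baseline for
recall@25 here is 25/250 = 0.1; all three solvers beat it several-fold,
and the two-step solver dominates (recall@25 of 0.87 versus 0.71–0.73 for
the one-shot solvers).

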