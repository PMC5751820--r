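---
title: "Robust inductive matrix completion: models, solvers and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust inductive matrix completion: models, solvers and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robimc)
```

## The problem

A binary association matrix $A \in \{0,1\}^{M \times N}$ records known links
between row entities (e.g. long intergenic non-coding RNAs) and column
entities (e.g. disease phenotypes). Such catalogues are extremely sparse and
incomplete: the absence of a link usually means *untested*, not *absent*.
The task is to rank, for each row entity, the unlinked columns by how likely
they are to be true associations — including for entities that have **no**
observed links at all (the cold-start case).

Inductive matrix completion (IMC) makes cold-start prediction possible by
modelling each cell through side-information features: with
$X \in \mathbb{R}^{M \times m}$ (row features) and
$Y \in \mathbb{R}^{N \times n}$ (column features),

$$A_{ij} \approx x_i^\top Z\, y_j, \qquad Z = W H^\top,$$

where $W \in \mathbb{R}^{m \times r}_{\ge 0}$ and
$H \in \mathbb{R}^{n \times r}_{\ge 0}$ are low-rank nonnegative factors.
Because $Z$ lives in *feature* space, a new entity only needs a feature
vector to be scored.

## The three solvers

**Standard IMC** (`fit_imc()`) minimizes
$$\tfrac12\lVert A - XWH^\top Y^\top\rVert_F^2
  + \tfrac{\lambda_1}{2}\lVert W\rVert_F^2
  + \tfrac{\lambda_2}{2}\lVert H\rVert_F^2, \quad W, H \ge 0,$$
by multiplicative updates derived from the KKT conditions,
$$W \leftarrow W \circ \frac{X^\top A Y H}
  {X^\top X W H^\top Y^\top Y H + \lambda_1 W}, \qquad
  H \leftarrow H \circ \frac{Y^\top A^\top X W}
  {Y^\top Y H W^\top X^\top X W + \lambda_2 H}.$$
Multiplicative updates preserve nonnegativity exactly and decrease the
objective monotonically; they require $A$, $X$, $Y$ to be nonnegative
(`shift_nonneg()` is provided for features with negative entries, e.g. SVD
coordinates, and must be applied explicitly because shifting changes the
affine geometry of the feature space).

**Robust IMC** (`fit_rimc()`) replaces every squared Frobenius norm with the
row-wise $\ell_{2,1}$ norm
$\lVert M\rVert_{2,1} = \sum_i \lVert M_{i\cdot}\rVert_2$:
$$\lVert A - XWH^\top Y^\top\rVert_{2,1}
  + \lambda_1 \lVert W\rVert_{2,1} + \lambda_2 \lVert H\rVert_{2,1}.$$
Because residual rows enter *unsquared*, a grossly corrupted row contributes
linearly rather than quadratically, damping its influence. The minimization
is by iteratively reweighted multiplicative updates: each iteration forms
diagonal weights
$$D_{ii} = 1/\lVert (A - XWH^\top Y^\top)_{i\cdot}\rVert_2,\quad
  P_{ii} = 1/\lVert W_{i\cdot}\rVert_2,\quad
  Q_{jj} = 1/\lVert H_{j\cdot}\rVert_2$$
from the current iterate and applies
$$W \leftarrow W \circ \frac{X^\top D A Y H}
  {X^\top D X W H^\top Y^\top Y H + \lambda_1 P W}, \qquad
  H \leftarrow H \circ \frac{Y^\top A^\top D X W}
  {Y^\top Y H W^\top X^\top D X W + \lambda_2 Q H}.$$
The weights are refreshed once per outer iteration, before the $W$ update,
and reused for the paired $H$ update; empirically the recorded
$\ell_{2,1}$ objective is non-increasing at every iteration under this
schedule (asserted to within $10^{-8}$ relative slack in the test suite).
`kkt_residual()` reports the scaled complementarity residual
$\max |(\nabla J)_{ik}\,W_{ik}| / \lVert A\rVert_F$ (and the analogue for
$H$) as a convergence diagnostic; at `tol = 1e-8` it drops below $10^{-4}$.

**Stable robust IMC** (`fit_srimc()`) decouples the problem into two steps,
each stable on its own:

1. *Closed form:* solve the feature-space normal equations
   $X^\top X\, Z\, Y^\top Y = X^\top A Y$, i.e.
   $\hat Z = (X^\top X)^{-1} X^\top A Y (Y^\top Y)^{-1}$ (`solve_Z()`).
   The Gram systems are solved with a linear solver, never an explicit
   inverse; an optional ridge (default $10^{-8}\,\mathrm{tr}(G)/\dim G$)
   stabilizes nearly collinear features, and near rank-deficiency is
   flagged. When $A = X Z^* Y^\top$ exactly and the features have full
   column rank, $\hat Z$ recovers $Z^*$ to machine precision.
2. *Robust NMF:* clamp $\hat Z$ at zero (`clamp_nonneg()`; the flag records
   whether clamping occurred) and minimize
   $\lVert Z - WH^\top\rVert_{2,1} + \lambda_1\lVert W\rVert_{2,1}
   + \lambda_2\lVert H\rVert_{2,1}$ by the same reweighted updates with
   $X = I$, $Y = I$ (`fit_robust_nmf()`). The specialized updates agree
   with the general ones entrywise to floating-point rounding.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rank` | 5 | factorization rank $r \le \min(m, n)$ |
| `lambda1`, `lambda2` | 0.01 | $\ell_{2,1}$ (or ridge) penalty weights on $W$, $H$; unitless, on the scale of the loss |
| `max_iter` | 500 | outer iteration cap |
| `tol` | $10^{-6}$ | stop when the relative objective change falls below this |
| `eps` | $10^{-10}$ | additive floor in update denominators (guards 0/0) |
| `weight_eps` | $10^{-8}$ | floor on row norms when forming $D$, $P$, $Q$ |
| `init` | `"uniform"` | `"uniform"` scaled random start, or `"nndsvd"` (nonnegative parts of leading singular triples) |

Two numerical choices deserve emphasis:

* **The reweighting floor is a smoothing parameter.** $1/\max(\lVert
  \cdot\rVert, \varepsilon)$ caps row weights at $1/\varepsilon$. In the
  sparse-binary ranking regime residual row norms stay $O(1)$ and the floor
  never binds. In *exact-recovery* regimes (factorizing a noiseless
  low-rank $Z$), rows that are already fit saturate at weight
  $1/\varepsilon$ and — at the default $10^{-8}$ — dominate the updates by
  seven orders of magnitude, freezing the remaining misfit rows at a few
  percent error. For such problems pass a moderate floor
  (`weight_eps = 1e-2`); the recovery tests do.
* **Zero is absorbing.** Multiplicative updates can never revive an exactly
  zero entry; initializations therefore keep all entries strictly positive
  (the `nndsvd` start adds a tiny seeded jitter for the same reason).

## What the synthetic generator emulates — and what it does not

`generate_planted_dataset()` builds, at desk scale, the structure of a
lincRNA-disease-style benchmark: nonnegative uniform features $X$
($M \times m$), $Y$ ($N \times n$), a planted nonnegative rank-$r$
coefficient matrix $Z^{*} = UV^\top$, a latent surface
$$S = \mathrm{standardize\_rows}(X Z^{*} Y^\top)
      + \texttt{noise\_frac}\cdot\mathcal N(0,1),$$
and $A_{ij} = 1$ on exactly the top `density`$\cdot MN$ cells of $S$
(global thresholding guarantees the requested sparsity). Row
standardization is deliberate: with all-positive factors the raw surface
$X Z^{*} Y^\top$ is nearly separable (rank-one-dominated), and global
thresholding would pile every association onto a few high-magnitude rows,
leaving half the rows empty — a regime in which the all-zero predictor is
the *true* $\ell_{2,1}$ optimum and nothing can be compared. Real
association catalogues have no empty rows (every listed entity has at least
one known link); standardization restores that property while leaving
within-row ranking — exactly what precision@k / recall@k measure —
untouched.

Defaults ($M{=}100$, $N{=}250$, $m{=}15$, $n{=}12$, $r{=}5$,
`density = 0.04`, `noise_frac = 0.1`) were chosen once as the package's
study conditions: dense enough that every row receives $\approx 10$
positives, and with enough columns that recall@25 has headroom over the
random baseline $k/N = 0.1$. `inject_outlier_rows()` replaces a fraction of
rows of $A$ with i.i.d. Bernoulli noise at `scale` times the base density,
decoupled from the planted structure — the row-wise corruption the
$\ell_{2,1}$ loss targets.

What the generator does **not** emulate: correlated real features (TF
binding sites, expression profiles, text TF-IDF after truncated SVD),
realistic 0.2%-scale sparsity, or the $10^3$–$10^4$ entity counts of real
catalogues. Passing tests therefore demonstrate the mechanics and relative
behaviour of the solvers under controlled planted structure, not absolute
performance on biological data.

## Evaluation protocol

Splits hide known positives; solvers are ranked by where the hidden
positives land. Conventions, fixed for bit-reproducibility:

* candidate columns for a row exclude its *training* positives (standard
  recommender evaluation; otherwise methods are rewarded for re-ranking
  known links);
* ties are broken by ascending column index;
* rows with no hidden positives are excluded from the average (recall is
  undefined for them);
* cross-validation partitions the *positive cells*; the three cold-start
  designs hold out whole rows, whole columns, or both, and the fit then
  drops the held entities from $A$ **and** from the feature matrices, so a
  held entity is scored purely from its features;
* in the column hold-out the hidden positives sit in held columns but are
  ranked against the full candidate set — ranking only the held columns
  would make recall@25 structurally saturated for any feasible hold-out
  size.

One protocol subtlety surfaced while designing the robustness comparison:
with 10-fold cross-validation each evaluated row has $\approx 1$ hidden
positive, so precision@10 is capped at $\approx 0.1$ for *every* method and
comparisons saturate. The packaged comparison therefore hides half the
positives (2-fold), giving the metric headroom; this choice is about the
measurement, not the methods.

## A worked example

```{r example, eval = FALSE}
ds <- generate_planted_dataset(list(seed = 1))
cfg <- train_config(rank = 5, lambda1 = 0.01, lambda2 = 0.01,
                    max_iter = 300, tol = 1e-6, seed = 1)
run_benchmark(c("imc", "rimc", "srimc"), ds, mode = "new_rows",
              k_grid = c(10L, 25L), n_repeats = 5L, seed = 1, config = cfg)
```

## Findings on the study conditions, and limitations

The test suite and `scripts/acceptance.R` compute all quantities quoted
here; none are asserted beyond what they measure.

* **The two-step solver is the strong performer.** SRIMC outranks both
  one-shot solvers with and without outliers (e.g. mean precision@10 about
  0.38–0.40 vs 0.27–0.29 under 10% outlier rows, and cold-start recall@25
  several times the random baseline in all three hold-out designs). Its
  closed-form first step is exact on planted data and immune to the slow,
  collapse-prone dynamics of the one-shot multiplicative updates on sparse
  binary targets.
* **Uniform row outliers barely bias the least-squares fit.** Rows replaced
  by uniform Bernoulli noise perturb the normal equations in a nearly
  separable (rank-one-like) direction, which is almost neutral for
  *within-row* ranking; standard IMC's precision is essentially unchanged
  by 10% such rows. The robust solver does down-weight the corrupted rows
  (their $D$ weights fall below the clean-row median) but gains no
  ranking advantage from it, and its inlier-emphasising weights — easy,
  well-fit rows get the largest $D$ — cost it a small amount of precision
  (about 0.015 at precision@10) relative to standard IMC under these
  conditions. Structured or feature-correlated corruption, which *can*
  bias a least-squares fit directionally, is the regime where row-robust
  losses should separate; the generator's decoupled-noise design does not
  produce it.
* **The $\ell_{2,1}$ objective on sparse binary matrices rewards predicting
  zero for empty rows** far more strongly than the squared loss does; any
  application of these solvers to a matrix with many all-zero rows should
  expect factor collapse toward the zero predictor (see the generator
  discussion above).
* Multiplicative updates converge sublinearly and can stall at local
  minima; for exact-recovery studies use the `nndsvd` start, a moderate
  `weight_eps`, and/or several seeded restarts.

Problem sizes throughout (tests and the acceptance script) are
$M \le 100$, $N \le 250$ with 20-seed batches — sizes at which a full
benchmark sweep completes in well under a minute while leaving every
qualitative property of the larger regime intact.
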