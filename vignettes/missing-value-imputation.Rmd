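---
title: "Handling missing values in MS-based metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling missing values in MS-based metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metimpute)
```

## The problem

Mass-spectrometry metabolomics tables (samples in rows, metabolites in
columns) almost always contain missing entries, and they arise from two
quite different mechanisms:

* **MCAR/MAR** — random failures during acquisition (incomplete
  derivatization or ionization) or preprocessing (peak picking,
  deconvolution of co-eluting compounds, alignment). These missing values
  are scattered over the table without regard to the underlying abundance.
  They are typical of untargeted GC/MS profiling data.
* **Left-censored MNAR** — the compound's abundance fell below the limit
  of quantification (LOQ), so missingness concentrates in the *low tail*
  of specific metabolites. Typical of targeted LC/MS panels (bile acids
  are a classic example, with serum concentrations spanning orders of
  magnitude).

Most multivariate workflows (PCA, PLS-DA) require a complete matrix, so
the missing entries must be imputed — and the right method depends on the
mechanism. `metimpute` provides both families of methods, simulators for
both mechanisms, and an evaluation pipeline that scores any method against
ground truth.

## Imputation methods

All eight methods sit behind `impute(x, method, ...)`. Every method
leaves observed entries bit-identical and returns a complete matrix.

**Determined-value methods** (`zero`, `hm`, `mean`, `median`) replace
each missing entry with a per-metabolite constant. Half-minimum (`hm`) —
half of the smallest observed value — is the conventional stand-in for a
below-LOQ measurement. These are cheap and stable, but they collapse all
missing entries of a metabolite onto one value, which distorts the
variable's distribution (visible in violin plots) and drags affected
samples onto a line in PCA score plots.

**kNN** (`impute_knn`, default `k = 10`) finds the k nearest *samples* by
Euclidean distance computed over the variables observed in both samples
and divided by the number of shared variables, then averages their values
at the missing position. Searching sample-space rather than
variable-space is the right orientation for metabolomics: unlike
microarray data with tens of thousands of co-expressed genes, a
metabolite panel is short, and similar samples are better predictors than
neighbouring metabolites. The spirit of the method assumes the missing
sample has close neighbours; it degrades as missingness grows.

**SVD** (`impute_svd`, default `k = 5`) reconstructs the matrix from its
top-k singular triplets, iterated to convergence, overwriting only the
missing cells. The matrix is column-standardised before each
reconstruction and the scaling parameters are recorded so the result can
be returned to the original scale exactly. Two numerical choices matter:

* *Per-sweep re-estimation of the column means/SDs.* We recompute the
  scaling from the current completed matrix at every sweep rather than
  once from the observed entries. With observed-only statistics, the
  centring leaves behind a rank-one residual (the gap between
  observed-subset means and full-column means), so even an exactly
  rank-k matrix cannot be completed exactly. With re-estimated
  statistics, the true completion is a fixed point of the iteration, and
  in practice the iteration converges to it: a masked entry of an exact
  rank-1 matrix is recovered to ~1e-7 relative error, and rank-5
  noiseless synthetic data to NRMSE ~1e-9 (both are tested).
* *Convergence.* The sweep loop stops when the relative L2 change of the
  imputed values drops below `tol` (default `1e-6`); the achieved
  accuracy tracks `tol`, so exactness checks use `1e-9`. Hitting
  `max_iter` produces a warning and is recorded in `params$converged`,
  not an error — a usable answer with a caveat beats none.

**RF** (`impute_rf`, default 100 trees) is the missForest scheme: start
from column means, visit metabolites in order of ascending missing
count, regress each on all others with a random forest, predict its
missing entries, and sweep until the scaled sum of squared changes first
increases (then keep the previous sweep). Forests capture the *nonlinear*
relations between metabolites — on the raw abundance scale the
relationships induced by correlated log-scale biology are monotone but
curved, which is exactly where RF beats linear low-rank reconstruction.
The forest engine is `ranger` on one thread with per-fit seeds drawn from
the seeded R RNG, so results are bit-reproducible.

**QRILC** (`impute_qrilc`) is the dedicated left-censored method. Per
metabolite: log-transform the observed values (improving the normal fit
and guaranteeing positive imputations); treat them as the upper
`q_obs = n_obs/n` fraction of a censored normal; regress the sorted
observed log-values on the standard-normal quantiles of their plotting
positions `(i - 0.375)/(n + 0.25)` (Blom's constants; conventions differ
between implementations, so they are exposed as `pp_offsets`) to estimate
the uncensored mean and SD; and draw each missing entry from that normal
truncated above at its `1 - q_obs` quantile — the estimated censoring
point. Unlike half-minimum, the draws repopulate the low tail and
preserve the variable's distribution. Metabolites with fewer than 5
observed values, or a non-positive fitted SD, fall back to half-minimum
with a warning rather than extrapolating from an unstable fit.

## Missingness simulators

`generate_mcar(x, proportion, seed)` masks exactly
`round(proportion * n * p)` entries uniformly at random (banker's
rounding, so the count is test-exact).

`generate_mnar(x, var_proportion, seed)` first selects
`round(var_proportion * p)` metabolites as missing variables, then draws
each one an independent censoring quantile `q ~ U(0.30, 0.60)` and masks
every entry *strictly below* the variable's empirical type-7 `q`-quantile.
Two conventions are fixed deliberately: the strict inequality makes the
left-censoring invariant exact (the largest masked value is always below
the smallest observed one), and variables are selected without regard to
abundance — the "low concentration" character of real below-LOQ
missingness is realised by censoring *within* each variable, not by
biasing which variables are picked. Because `q ≤ 0.60`, a variable can
never lose all entries; the generator still checks and errors if it ever
happened. The benchmark grids are 2.5%–50% in 2.5% steps (MCAR, fraction
of entries) and 4%–80% in 4% steps (MNAR, fraction of metabolites).

## Filtering: the modified 80% rule

Before imputing, metabolites that are mostly missing should be removed
outright. The plain 80% rule drops a metabolite observed in fewer than
80% of samples. The modified rule (`filter_missing_variables`, group-wise
by default when labels are given) drops it only when it is below the
threshold in *every* biological group — a metabolite fully observed in
cases but censored in controls is likely a real group difference, and
dropping it would discard exactly the differential signal one is looking
for. A metabolite exactly at the threshold is kept, and the threshold is
exposed as a 0–1 fraction. The recommended order of operations, which the
command-line tool follows, is: inspect raw data where possible → filter →
choose the method by mechanism (`recommend_method()`): QRILC for
left-censored MNAR, RF for MCAR/MAR.

## Evaluation framework

All metrics compare an imputed matrix against the complete ground truth.

* **NRMSE** — `sqrt(mean((true - imp)^2) / var(true))` over the masked
  entries, after column-standardising both matrices with the *complete*
  matrix's means and (n−1) SDs. Using the complete matrix's statistics
  for both sides isolates imputation error; z-scoring stops
  high-abundance metabolites from dominating. A useful fixed point of
  the metric: an imputation that always answers the column mean has
  numerator ≈ denominator, so its NRMSE plateaus at 1 — mean/median
  imputation define the "no information" baseline.
* **SOR** — per-variable NRMSEs are ranked across methods (average ranks
  on ties) and summed per method. Rank sums over J methods and M
  variables always total `M·J·(J+1)/2`, a conservation law the tests
  exploit. SOR is the preferred summary for MNAR, where the skewed
  per-variable error distribution biases pooled NRMSE in favour of
  determined-value methods.
* **PCA/PLS-Procrustes** — score configurations (top 2 components;
  PLS-DA via `mixOmics` for the supervised case) of complete and imputed
  data are compared by symmetric Procrustes superimposition
  (`vegan::procrustes`), which removes translation, rotation, reflection
  and isotropic scaling — so PCA's inherent sign/rotation ambiguity
  cannot leak into the score. The residual sum of squares lies in [0, 1],
  comparable across missing proportions.
* **log-p correlation** — per metabolite, two-sample Student's t-tests
  (pooled variance; a Welch flag is available since the classical
  description leaves this open) on complete and imputed data; Pearson r
  between the two log-p vectors. p-values are logged because of their
  skew; the log base is irrelevant to Pearson r (natural log is used).
  For MNAR evaluation the correlation is restricted to the censored
  variables; for MCAR all variables are used (scattered missingness
  touches most variables anyway).

`run_benchmark()` wires these together: per missing proportion and
repeat, one mask is generated and *every* method imputes that same mask,
so cross-method comparisons are paired; metrics are averaged over
repeats (default 3 — a deliberate engineering addition so stochastic
methods are compared on more than one realisation; each repeat `r` uses
seed `base_seed + r` for generator and imputers alike).

## The synthetic data generator

`generate_complete(synth_spec(...))` draws
`log X = 1·o' + S·W + Δ + E`: per-metabolite baseline offsets
`o ~ U(1, 5)` so columns span concentration ranges (this is what makes
z-scored evaluation meaningful), standard-normal scores and loadings of
rank `latent_rank` (default 5, matching the SVD imputer's default),
an optional log-scale shift of `effect_size` on `n_affected` metabolites
in the second of two balanced groups, and Gaussian noise (`noise_sd`,
default 0.1 — small relative to the ~2.2 log-units of factor-driven
spread, i.e. strongly correlated metabolite panels). Exponentiation
yields positive, right-skewed abundances with nonlinear (monotone)
dependencies on the raw scale.

What the generator emulates: positivity, right skew, low-rank
correlation structure, group effects, per-metabolite abundance ranges —
the features the benchmark metrics are sensitive to. What it does not:
instrument drift, batch effects, QC samples, heteroscedastic
(intensity-dependent) noise, or non-normal log-abundance shapes. Passing
benchmarks on this generator therefore demonstrates correct mechanics
and the expected *ordering* of methods under the stated mechanisms, not
performance guarantees on any particular instrument's data.

Default study sizes used in the tests and the acceptance script —
100 samples × 50 metabolites for the method-ranking benchmarks (3
proportions per mechanism, 2–3 repeats), 200 × 50 for the
mean-imputation plateau — are the package's choice of a medium-sized
clinical metabolomics study that still exercises every code path.

## Known limitations

* QRILC is fit per metabolite, which matches a variable-wise LOQ (the
  censoring point is a property of the compound and assay). Proteomics
  implementations often fit per sample-column instead; that variant is
  not provided.
* The RF stopping rule keeps whole sweeps; it does not track per-variable
  convergence.
* kNN distances are computed on the raw scale; with very wide abundance
  ranges the largest metabolites dominate the neighbour search. This is
  the method's classical form and contributes to its degradation at high
  missingness.
* No multiple imputation: every method returns a single completed
  matrix without uncertainty propagation.

## A worked example

```{r example, eval = FALSE}
d <- generate_complete(synth_spec(n_samples = 100, n_metabolites = 50,
                                  seed = 1))
ds <- generate_mnar(d$matrix, var_proportion = 0.4, seed = 2)
cfg <- benchmark_config("mnar", proportions = 0.4, n_repeats = 2,
                        base_seed = 42, metrics = "sor")
run_benchmark(d$matrix, config = cfg)
```
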