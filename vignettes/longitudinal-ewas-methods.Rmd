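---
title: "Longitudinal modelling strategies for EWAS: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal modelling strategies for EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longewas)
```

## The problem

DNA methylation at a CpG site changes with age, and an exposure (say,
prenatal smoking) can shift a child's methylation trajectory in several
qualitatively different ways: a constant offset, divergence over time from a
common starting point, convergence back towards the unexposed group, or
combinations of these. Cross-sectional EWAS — one regression per CpG at one
time-point — only ever sees a slice of that trajectory. Modelling the
repeated measures jointly sees the whole shape, but a linear mixed model per
CpG is expensive when there are hundreds of thousands of CpGs.

`longewas` implements and compares the candidate strategies:

* cross-sectional EWAS at each wave, with three hit-selection rules
  (associated at **baseline**, at **any** time-point, at **all**
  time-points);
* a per-CpG **linear mixed model** with a random intercept, or a random
  intercept and age slope (the flexible but slow comparator);
* **linear regression with cluster-robust standard errors** across all
  repeated measures — ordinary least squares per CpG, with the
  within-individual correlation absorbed by a sandwich variance estimator
  rather than by random effects. This is the fast longitudinal method the
  package is built around.

## The trajectory model

For methylation `y_ij` of individual `j` at measurement `i`, age `x_ij`
(centred at the baseline age so the intercept parameters are baseline
quantities) and binary individual-level exposure `z_j`:

```
y_ij = (b00 + b01 z_j + u0j) + (b10 + b11 z_j + u1j) x_ij + e_ij
```

with `(u0j, u1j) ~ N(0, Sigma_u)` (unstructured 2x2 covariance),
`e_ij ~ N(0, sigma_e^2)`. The two scientifically interesting parameters are
`b01`, the exposure effect at baseline, and `b11`, the exposure effect on
the yearly rate of change.

The **mixed-model route** (`fit_lmm()`, `fit_lmm_batch()`) estimates this
model by REML through `lme4::lmer()`; the random-effect covariance is kept
positive semidefinite by lme4's Cholesky parameterisation, and a variance
component estimated on the zero boundary is reported with status
`"boundary"` (never silently swapped for the simpler model: the
intercept-only and intercept+slope fits are distinct strategies and are
compared as such). Wald p-values use the standard normal reference; with
several hundred independent individuals per fit the difference from a t
reference is negligible, and using the same rule as the robust fit makes
the two methods directly comparable.

The **robust-regression route** (`fit_robust()`) fits the same mean
structure by OLS, sharing one QR factorisation across all CpGs with
complete data, and estimates the coefficient covariance per CpG as

```
V = (X'X)^-1 [ sum_j w_j' w_j ] (X'X)^-1 ,   w_j = sum_{k in j} e_k x_k
```

where the sum over `j` runs over individuals (clusters) and `e_k` are the
OLS residuals. The meat accumulation is vectorised across CpGs in compiled
code (RcppArmadillo), which is what makes the method practical at
epigenome scale. With every cluster of size one the estimator reduces to
HC0, which the test suite exploits as an oracle. No finite-sample
correction is applied by default — the estimator is used in a regime of
hundreds of clusters where corrections are negligible — but the CR1 factor
`m/(m-1)` is available via `small_sample_correction`, and a
`t(m - p)` reference via `df_method = "t_clusters_minus_p"`.

Under a balanced complete panel (every individual measured at the same
ages) the OLS and GLS fixed-effect estimates coincide, so the two
longitudinal routes return essentially identical point estimates and differ
only in how they estimate uncertainty. The test suite checks this identity
directly; it is also why the package's simulator, which generates balanced
panels, shows estimate correlations of ~1.0 between the two methods.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `significance_threshold` | `1e-7` | epigenome-wide (Bonferroni-style) hit threshold |
| `age_origin` | min age present | age (years) at which `b01` is evaluated |
| `small_sample_correction` | off | CR1 meat factor `m/(m-1)` |
| `df_method` | `normal` | Wald reference distribution |
| `age_tolerance` | `0.5` y | window for matching observations to a wave in cross-sectional EWAS (real cohorts have age jitter; simulated ages match exactly) |

## What the simulator emulates

`simulate_dataset()` draws balanced panels from the trajectory model
itself: `n_individuals` (default 464) each observed at `repeats` equally
spaced ages between 10 and 18 years (3, 5 or 9 occasions; 5 is the primary
design), binary exposure with prevalence 0.5, 100 CpGs per replicate of
which 6 carry an exposure effect — one per causal pattern:

* **(i)** constant offset, no age trend (`b01 != 0`);
* **(ii)** diverging from a common baseline, flat unexposed trajectory
  (`b11 != 0` only);
* **(iii)** diverging from a common baseline on top of an age trend
  (`b10, b11 != 0`);
* **(iv)** constant offset plus an age trend (`b01, b10 != 0`);
* **(v)** baseline effect and divergence (`b01, b11 != 0`);
* **(vi)** baseline effect converging over time (`b11` of opposite sign,
  constrained so the groups do not cross within the age span).

The remaining 94 CpGs are null for the exposure (`b01 = b11 = 0`) but keep
their own baseline level (uniform on 0.2–0.8) and a small per-CpG age trend
(SD 0.0015/y) — age-related drift is ubiquitous in methylation and a null
CpG should not mean a flat one.

Default magnitudes are the package's own synthetic choices, set once to
make the design behave like a realistically powered adolescent-cohort
study: `b01 = 0.02` (two percentage points of methylation at baseline),
`b11 = 0.004`/y (`-0.00125`/y for the converging scenario), `b10 = 0.002`/y
where present; random-effect SDs 0.025 (intercept) and 0.007/y (slope) with
correlation −0.2, residual SD 0.0325. At `n = 464` and five waves these
imply Wald SEs of roughly 0.003 for `b01` and 0.0008 for `b11`, so both
parameters sit a few SDs beyond the epigenome-wide threshold — detectable
but not saturated, which is the informative regime for comparing
strategies.

What the simulator deliberately does **not** emulate: array noise
structure, batch effects, cell-composition signal, probe artefacts, missing
visits, or the bounded support of beta values (simulated values are
Gaussian and not clipped by default, because clipping would bias the
parameter-recovery checks; a `clip_beta` option exists for users who want
bounded values). Passing tests therefore demonstrate correctness of the
estimators under the generative trajectory model, not robustness to
array-level artefacts — those are handled upstream by normalisation
pipelines in real analyses.

## Numerical choices and degenerate inputs

* OLS is solved by QR throughout; a design condition number above 1e8
  additionally triggers a warning. Rank deficiency (e.g. a constant
  exposure) is an error naming the collinear column.
* A CpG with missing values is refitted on its complete rows only, with its
  own bread matrix and its cluster count `m` recomputed; CpGs with complete
  data share one factorisation. Correctness is preferred over uniform
  speed.
* `m <= p` clusters, or fewer usable rows than parameters, flag the CpG as
  unfit/unreliable rather than crashing the batch.
* Zero standard errors are resolved deterministically: estimate 0 gives
  p = 1, a nonzero estimate gives p = 0 with a warning.
* Mixed-model fits that fail (constant outcome, degenerate covariance) are
  isolated per CpG with status `"failed"` and excluded — and counted — by
  hit selection.
* Seeds: every replicate's stream is derived from the master seed and the
  replicate index by a counter-based map (`derive_seed()`), so results are
  independent of execution order and reproducible byte-for-byte.

## Evaluation harness and problem sizes

`compare_strategies()` runs the full loop — simulate, fit all requested
strategies, classify hits, aggregate — and reports power per (strategy,
scenario), Type I error per strategy pooled over null CpG × replicate
tests, relative bias `(bhat - b)/b` of `b01` and `b11` (undefined, hence
`NA`, where the true value is zero; quantiles reported at 2.5%/97.5%), and
a methods-equivalence table for the two longitudinal routes.

The package's own validation runs use deliberately chosen scales: bias is
assessed over 200 replicates of the six causal CpGs at the full `n = 464`
design; Type I calibration uses 500 null CpGs; power orderings use 100
replicates per repeats setting. At these sizes the Monte-Carlo SE of a
power estimate is at most 0.05, sufficient for the directional claims being
checked, while a full reproduction at 1000 replicates × 100 CpGs is a
straightforward (if slow) configuration change.

One caveat worth knowing: the relative bias of the converging scenario's
interaction is intrinsically noisy because the true `b11` is small — its
per-replicate relative bias has SD ≈ 0.6, so summaries of that single cell
need several hundred replicates before Monte-Carlo noise stops dominating.

## Known limitations

* Exposure is binary in everything that is tested; continuous exposures run
  through the same code path but are not validated against the package's
  claims.
* No working-correlation structures beyond independence (this is OLS +
  sandwich, not GEE), no >2-level clustering, no non-Gaussian outcomes.
* Cross-sectional EWAS uses classical SEs (exact under singleton clusters
  up to the HC0 distinction, which the tests quantify).
* No multiplicity handling beyond the fixed threshold; no FDR.
* Surrogate-variable / cell-composition adjustment is out of scope; named
  numeric covariates from the sample sheet are supported.

## A minimal session

```{r example, eval = FALSE}
cfg <- simulation_config(n_individuals = 200, seed = 1)
sim <- simulate_dataset(cfg, replicate_index = 1)

fit <- fit_robust(sim$dataset)
results <- as_result_table(fit)
hits <- select_hits(results, "robust_lm", analysis_config())

lmm <- fit_lmm_batch(sim$dataset, random = "intercept_slope")
head(as_result_table(lmm))

res <- compare_strategies(cfg, analysis_config(significance_threshold = 0.05),
                          n_replicates = 20)
res$power
```
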