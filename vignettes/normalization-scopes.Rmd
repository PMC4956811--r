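---
title: "Normalization scopes for platelet-function time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization scopes for platelet-function time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfnorm)
```

## The model

A perioperative platelet-function study is a set of measurements indexed by
patient, ordered sampling moment (S1 baseline before incision, S2 after
weaning from cardiopulmonary bypass, S3 at 24 h), and attribute — an
assay·parameter pair such as `PlatCt` (platelet count, ×10⁹/L) or
`MCF EXTEM` (maximum clot firmness of the tissue-factor ROTEM channel, mm).
`pfnorm` keeps these records in tidy long format: missing measurements are
absent rows, never sentinel values, so no group statistic is ever
contaminated by placeholders.

Four rescaling transforms are provided. For a group of values $X$ with mean
$u$, sample standard deviation $s$ (the $n-1$ denominator — the clinical
statistics default; the population variant is a documented one-line change),
quartiles $Q_1, Q_3$ and median $m$:

* z-transform $Z = (X - u)/s$;
* range transform $y = \mathrm{lo} + (X - \min)(\mathrm{hi} -
  \mathrm{lo})/(\max - \min)$, default $[0, 1]$;
* proportion transform $y = X / \sum X$;
* interquartile-range scaling $y = (X - m)/(Q_3 - Q_1)$.

The interquartile-range method is named by its scale criterion only;
centering is not prescribed anywhere, so this package implements the
standard robust-scaling companion — centering at the median — and documents
that as an interpretation. Quantiles use linear interpolation between order
statistics (R's type 7), fixed for reproducibility.

Each transform runs under one of three **scopes**, which decide the group
over which $u, s, \min, \max, Q_1, Q_3, m, \sum$ are computed:

* `all` — one group containing every value;
* `per_attribute` — one group per attribute, pooling all patients and all
  time points;
* `per_timepoint` — one group per sampling moment, pooling all patients and
  all attributes.

A fourth scope (per attribute *and* per time point) is deliberately not
offered: with the three-moment design it would normalize each assay's
timepoint cell in isolation and erase the temporal signal entirely.

## Why the scope decides everything

Within a group, all four transforms (z and iqr always; range with
$\mathrm{lo} < \mathrm{hi}$; proportion when the group sum is positive) are
strictly increasing affine maps. Under `per_attribute` every value of an
attribute lives in one group, so the attribute's ranks — and therefore every
Spearman coefficient between attributes — are preserved *exactly*, tie
structure included. Under `per_timepoint` each moment gets a different
affine map; within-moment ranks survive but the interleaving of values
across moments is rearranged, and pooled cross-attribute correlation is
distorted or destroyed. The package's acceptance suite asserts both
directions: bit-stability of $\rho$ under per-attribute z/range/iqr, and a
material change ($|\Delta\rho| > 0.1$ for the platelet-count/EXTEM pair
under the range method) under per-timepoint normalization on the seeded
synthetic study. Proportion scaling is also rank-preserving per attribute,
but it collapses all attributes onto comparable tiny magnitudes whose
*visual* spread no longer reflects the correlation — the reason it fails as
a visualization even under the favourable scope.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `range_lo`, `range_hi` | 0, 1 | target interval of the range method |
| `clamp_z` | off (`b = 3` when enabled) | clip z-scores to $[-b, b]$; ±3 retains ~99.9% of Gaussian data. Off by default because clipping destroys tail monotonicity and with it the rank-preservation guarantee |
| `degenerate` | `"skip"` | a constant group (zero sd, max = min, zero IQR, zero sum) carries no ordering information; skipping (emit as missing, warn) beats failing a 150-attribute run. `"zero"` and `"error"` available |
| PLTEM parameter families | A5, A10, A20, Alpha, MCF | amplitude/kinetics families where EXTEM − FIBTEM is clinically meaningful; clotting times and lysis are excluded by default (subtracting times has doubtful meaning) but the list is overridable |
| strength bands | strong $|\rho| > 0.40$; moderate $0.30 \le |\rho| \le 0.40$ | the published bands leave $(0.39, 0.40]$ unassigned; assigning it to "moderate" tiles $[0, 1]$ with the smallest deviation from the printed thresholds |
| `p_method` | `t_approx` | $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df; `exact_perm` enumerates all $n!$ rank permutations (refused above $n = 8$, and refused under ties, where the enumeration null is ill-defined — it falls back to the t approximation with a warning). Worst-case disagreement between the two nulls, computed by full enumeration: 0.15, 0.077, 0.048, 0.027 for $n = 4 \ldots 7$ |
| trend `degree` | 2 | the maximum a 3-timepoint axis supports; time is the integer index of the ordered moments, not elapsed hours, because the S1/S2/S3 axis is categorical-ordered |

Correlation uses pairwise deletion of incomplete pairs (maximizing $n$ in a
20-patient cohort) and is computed on raw values by default — normalization
serves visualization, and the per-attribute invariance means the coefficient
would be identical anyway. No multiple-testing correction is applied.

## The synthetic world

The generator emulates the cohort the methods were developed on: 20
patients × 3 moments, marginals read from clinical normal ranges as central
95% intervals of a normal distribution truncated at physiologic zero
(mean at the range midpoint, sd = (hi − lo)/3.92):

* `PlatCt` 150–450 ×10⁹/L,
* `MCF FIBTEM` 9–25 mm (the standard FIBTEM reference interval),
* `MCF PLTEM` 35–45 mm,
* `MCF EXTEM` emitted as FIBTEM + PLTEM, which lands in the published
  49–71 mm normal range and makes `derive_pltem()` an exact inverse.

Rank correlation is imposed by a Gaussian copula: Spearman targets are
converted to latent Pearson correlations via $r = 2\sin(\pi\rho_s/6)$,
the latent matrix is validated for positive semi-definiteness (with a
nearest-PSD eigenvalue-clipping repair and warning otherwise, unspecified
pairs completed with zeros), and uniforms are pushed through each marginal's
truncated-normal quantile function. Because EXTEM is a sum rather than a
copula column, its correlation with platelet count cannot be set directly;
`solve_fibtem_target()` solves, on the latent scale, for the
(PlatCt, FIBTEM) target that induces the requested (PlatCt, EXTEM)
correlation — defaults anchor the two headline pairs at 0.749 (strong)
and 0.067 (weak).

Time is a multiplicative profile on the marginal *mean* only, leaving the
copula — hence within-moment rank structure — untouched, so trend and
correlation are independently testable. The default profiles encode the
qualitative perioperative course with attribute-specific shapes: platelet
count dips to 60% after bypass and partially recovers (1.0, 0.6, 0.8);
FIBTEM dips with hemodilution and overshoots at 24 h with the acute-phase
fibrinogen response (1.0, 0.8, 1.1); PLTEM stays flat (1.0, 1.0, 1.0). A
single shared dip profile would be wrong twice over: it would mechanically
inflate the *pooled* platelet-count/PLTEM correlation to ~0.36 — the
clinical finding this world emulates is that PLTEM is largely independent of
platelet count (r = 0.067) — and it would impose a 40% drop in clot
amplitude, far beyond what post-bypass ROTEM shows. These values were fixed
once, from clinical reasoning, and are configurable per attribute.

Values are rounded to whole units by default (platelet counts and ROTEM
amplitudes are reported at integer resolution), which has the welcome side
effect of making EXTEM − FIBTEM = PLTEM exact in floating-point arithmetic;
`round_digits` is configurable.

```{r demo}
study <- generate_study(synthetic_config(seed = 42))
round(study$report$realized_spearman, 3)
```

### What a green test does not establish

The generator reproduces marginal location/scale, pairwise rank structure
and a mean time-course. It does **not** model within-patient serial
correlation (all 60 samples are exchangeable draws), measurement error
structure, skewed or heavy-tailed clinical marginals, informative
missingness (`inject_missing()` drops rows independently), or any
mechanistic coagulation physiology. Passing tests establish the *methods'*
properties — rank preservation, scope effects, estimator calibration — not
clinical validity of any particular dataset.

## Numerical choices

* Degenerate groups: see the `degenerate` policy above; the run report
  (`normalization_report()`) lists every skipped group with its statistics.
* The copula factorization uses the symmetric eigendecomposition rather
  than Cholesky so repaired semi-definite matrices are accepted.
* Trend fits solve the polynomial normal equations on the raw power basis
  (degree ≤ 2 on a 3-point axis poses no conditioning risk); $R^2$ of a
  constant attribute is defined as 0.
* With exactly degree + 1 distinct time indices, least squares interpolates
  the per-index pooled means; the acceptance suite checks this identity
  numerically. Model df = degree + 1 by convention.
* Reproducibility: every stochastic entry point takes an explicit seed;
  the pipeline writes a manifest (seed, config, package version) and
  reruns are byte-identical on all CSV/JSON artifacts.

## Known limitations

* Adaptive (moving-average) normalization for non-stationary series is out
  of scope — meaningless with three time points.
* Log transformation is not offered; the four methods above are the
  package's subject.
* Exact permutation p-values are factorial-time and capped at $n = 8$;
  beyond that the t approximation is adequate (worst-case error shrinks
  with $n$).
* The strength bands and the ±3 z-window are conventions of the clinical
  source material, not estimator theory.
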