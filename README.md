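# pfnorm

Normalization methods for multivariate platelet-function time series.

## The problem

Perioperative hemostasis monitoring produces panels in which each patient at
each sampling moment is described by dozens of attributes on wildly
different native scales: platelet count (PlatCt, hundreds of ×10⁹/L),
ROTEM clot amplitudes (tens of mm), aggregometry responses (% or U). Plotted
or mined together without rescaling, the large-scale attributes flatten
everything else and genuine cross-assay relationships are invisible. But the
*grouping scope* of the normalization decides what survives:

* **per attribute** (statistics pooled over all patients and time points,
  one group per assay) — every transform considered here is a strictly
  increasing map within the group, so each attribute's ranks are untouched
  and Spearman correlation between attributes is preserved *exactly*;
* **per time point** (statistics pooled over all attributes within a
  sampling moment) — each time point gets a different map, cross-timepoint
  rank structure is scrambled, and correlation visible in the raw data is
  destroyed;
* **whole dataset** — a single global affine map; ranks survive but the
  scale separation between attributes remains, so nothing becomes visible.

`pfnorm` implements the four transforms, the three scopes, and the
surrounding analysis, so the scope effect can be demonstrated and tested on
synthetic data that emulates a 20-patient cardiopulmonary-bypass cohort
sampled at S1 (baseline), S2 (post-bypass) and S3 (24 h postoperative).

## Methods

For a group of values X with mean u, sample sd s, quartiles Q1/Q3, median m:

| method       | formula                            | post-condition            |
|--------------|------------------------------------|---------------------------|
| `z`          | Z = (X − u) / s                    | mean 0, sd 1              |
| `range`      | lo + (X − min)(hi − lo)/(max − min)| min = lo, max = hi        |
| `proportion` | X / sum(X)                         | sums to 1                 |
| `iqr`        | (X − m) / (Q3 − Q1)                | median 0, IQR 1           |

Derived ROTEM parameter: `X PLTEM = X EXTEM − X FIBTEM`, the platelet
contribution to clot firmness. Spearman rank correlation with strength
labels strong (|r| > 0.40), moderate (0.30 ≤ |r| ≤ 0.40), weak; two-sided
p-values from the Student-t approximation or exact permutation enumeration.
Pooled polynomial trends over the ordered time index with model df =
degree + 1. A Gaussian copula (latent correlation 2·sin(π·ρ_s/6)) generates
synthetic studies with prescribed marginal normal ranges and Spearman
targets.

## Worked example

```r
library(pfnorm)

study <- generate_study(synthetic_config(seed = 42))
t <- study$table            # 240 rows: 20 patients x 3 timepoints x 4 attributes
w <- pivot_wide(t)

spearman_rho(w$PlatCt, w[["MCF EXTEM"]])
#> [1] 0.7904706
spearman_rho(w$PlatCt, w[["MCF PLTEM"]])
#> [1] 0.1211355
```

Platelet count correlates strongly with the tissue-factor clot amplitude
(EXTEM MCF) and only weakly with the platelet-isolated PLTEM amplitude —
the synthetic world mirrors the clinical finding (published r = 0.749
strong, r = 0.067 weak). Normalizing per attribute leaves these
coefficients bit-identical; normalizing per time point does not:

```r
n1 <- normalize(t, normalization_spec("z", "per_attribute"))
w1 <- pivot_wide(n1)
spearman_rho(w1$PlatCt, w1[["MCF EXTEM"]])
#> [1] 0.7904706            # unchanged to machine precision

n2 <- normalize(t, normalization_spec("range", "per_timepoint"))
w2 <- pivot_wide(n2)
spearman_rho(w2$PlatCt, w2[["MCF EXTEM"]])
#> [1] 0.533565             # correlation degraded by the scope choice
```

Full pipeline (12 normalized tables = 4 methods × 3 scopes, correlation and
trend CSVs, faceted SVG figures, reproducibility manifest):

```r
run_pipeline(run_config(out_dir = "demo_run", seed = 42))
```

or from the shell:

```sh
Rscript inst/cli/pfnorm.R run --demo --seed 42 --out-dir demo_run
Rscript inst/cli/pfnorm.R simulate --seed 1 -o study.csv
Rscript inst/cli/pfnorm.R normalize --method iqr --scope per-attribute -i study.csv -o norm.csv
Rscript inst/cli/pfnorm.R correlate -i study.csv --targets "MCF EXTEM,MCF PLTEM" --references PlatCt -o corr.csv
```

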