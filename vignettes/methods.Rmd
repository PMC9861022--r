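---
title: "Surrogate insulin-resistance indices and metabolic syndrome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate insulin-resistance indices and metabolic syndrome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsynir)
```

## The scientific problem

Insulin resistance (IR) is rarely measured directly in large occupational or
primary-care cohorts: clamp studies are impractical and fasting insulin is
seldom assayed. Surrogate indices built from routine fasting chemistry and
anthropometry stand in for it. This package implements six of them —

* **TG/HDL**: fasting triglycerides over HDL cholesterol (both mg/dL),
  high-risk above 2.4 (strict, reading "over 2.4" literally);
* **TyG**: `ln(TG × glucose / 2)`, high-risk from 8.8 (inclusive);
* **TyG-BMI**, **TyG-waist**, **TyG-WtHR**: TyG multiplied by BMI (kg/m²),
  waist circumference (cm) and waist-to-height ratio (dimensionless, both
  lengths in cm);
* **METS-IR**: `ln(2·glucose + TG) × BMI / ln(HDL)`, high-risk from 50
  (inclusive).

together with Friedewald LDL (`total cholesterol − HDL − TG/5`, valid only
for TG < 400 mg/dL; missing above) and rule-based metabolic-syndrome (Met-S)
classification under three criteria sharing the component cut-offs
TG ≥ 150 mg/dL, HDL < 40/50 mg/dL (men/women), BP ≥ 130/85 mmHg and glucose
≥ 100 mg/dL:

| Criterion | Waist cut-off (M/F, cm) | Rule |
|---|---|---|
| NCEP/ATP-III | > 102 / > 88 | any 3 of 5 |
| IDF | ≥ 94 / ≥ 80 | waist mandatory + ≥ 2 others |
| JIS | ≥ 94 / ≥ 80 | any 3 of 5 |

Two consequences follow from the rules alone and are property-tested: an
IDF-positive subject always has elevated waist, and (because the JIS waist
cut-offs are lower with all other cut-offs shared) every ATP-III-positive
subject is JIS-positive.

The published METS-IR formula circulates with unbalanced parentheses; we use
the original definition `(ln(2·G + TG) · BMI) / ln(HDL)`, the only reading
whose values (roughly 30–55 in adults) match reported group means — the
literal alternative `ln((2·G + TG) · BMI) / ln(HDL)` sits near 2.4 for any
plausible adult. Classification is measurement-only: the cohort schema
carries no treatment fields, so drug-treated hypertension or diabetes cannot
count as positive components. This is a deliberate divergence from the full
published criteria and will under-classify treated subjects in real data.

Boundary conventions ("over" strict, "from" inclusive; ATP-III waist strictly
above 102/88, IDF/JIS inclusive at 94/80) are configuration, not facts about
any particular dataset: `index_thresholds()` and `mets_criteria()` expose
every cut-off, so e.g. the original ATP-III glucose ≥ 110 dialect is a
one-argument change.

## The synthetic cohort generator

Large occupational datasets of this kind are not shared, so the package
ships a seeded generator whose defaults reproduce the sex-stratified
characteristics of a Spanish working-age population of 418,343 subjects
(58.8% men, 33.2% smokers; men e.g. waist 86.2 (SD 11.1) cm, TG 123.7 (86.4)
mg/dL; women waist 74.8 (10.6) cm, TG 89.1 (46.2) mg/dL; age limited to
18–67). The generation model, per sex:

1. draw a latent multivariate Gaussian with a fixed correlation matrix;
2. map each coordinate through its marginal — Gaussian for height, weight,
   waist, blood pressure, cholesterol and HDL; moment-matched log-normal for
   triglycerides and glucose, which are right-skewed (the male TG SD is 70%
   of its mean, impossible for a positive Gaussian without heavy truncation);
3. reject and redraw rows outside physiological bounds or with SBP ≤ DBP;
4. draw age uniformly within a sampled age band (only band frequencies are
   published), smoking and social class per sex, and derive LDL by
   Friedewald (missing at TG ≥ 400).

A Gaussian copula is the simplest mechanism that reproduces marginals plus a
correlation structure. No correlation matrix is published, so the default is
a set of mid-range literature values — waist–weight 0.85, waist–TG 0.35,
waist–glucose 0.30, waist–SBP 0.30, TG–glucose 0.30, TG–HDL −0.40, SBP–DBP
0.70, 0.15 among the remaining risk variables, height independent of all —
chosen once to make waist the strongest single correlate of the metabolic
axis, and fully overridable (`default_spec(correlation = ...)`). Weight is
generated and BMI derived, never the reverse, so weight and BMI cannot be
double-specified.

Truncation bounds: three were fixed at the design stage (glucose 50–400,
HDL 15–130, waist 50–160); the rest are wide physiological ranges.
Triglycerides use 10–1000 mg/dL: a floor as high as 30 mg/dL would cut ~2.7%
of the male log-normal's lower tail and bias the mean upward by more than the
generator's own 1.5% calibration contract, while at 10 mg/dL the truncated
mass is negligible. Residual truncation bias is largest for female weight
(~1%, from the weight floor compounded by the correlated waist floor) and
stays inside the contract: at n = 50,000 every per-sex mean is recovered
within 1.5% relative error, every SD within 5%, and categorical proportions
within ±0.01 (asserted in the test suite at a fixed seed).

**What the generator does not emulate**: occupational sector and region,
device measurement error, intra-subject variability, missingness other than
Friedewald-invalid LDL, treated disease, and any non-Gaussian dependence
(tail dependence, nonlinear coupling). Passing structural tests on this
cohort therefore shows the pipeline's logic and calibration are correct, not
that the published effect sizes are reproduced — those require the original
data.

## ROC curves, AUC and cut-points

All six scales are treated as risk-increasing (group means are higher in
every Met-S-positive group) and predicted-positive means score ≥ threshold.
ROC points sweep thresholds downward over distinct scores with ties grouped.
The AUC is computed as the Mann–Whitney concordance probability via midranks
(concordant pairs + half of ties over all case–control pairs), which equals
the trapezoidal area under the ROC polygon — both routes are computed and
their equality to 1e-12 is property-tested. Confidence intervals use the
DeLong variance estimator computed from placement values (O(n log n) through
midranks), with Hanley–McNeil as a configurable alternative; intervals are
clipped to [0, 1].

The Youden-optimal cut-point maximises J(t) = sensitivity + specificity − 1
over all midpoints between adjacent distinct scores plus the two extremes;
ties in J break toward the lowest cut-off, which maximises sensitivity. The
sweep is verified against exhaustive search on random inputs. With the ≥
convention a degenerate input whose best J is 0 (e.g. perfectly interleaved
scores) reports the −Inf extreme: every subject predicted positive,
sensitivity 1, specificity 0.

`run_roc_battery()` produces the full 6 scales × 3 criteria × 2 sexes = 36
entry layout; a stratum with a single-class outcome is flagged
not-computable and the rest are still produced.

## Odds ratios and descriptive statistics

`fit_logistic()` is iteratively reweighted least squares with step-halving
(the log-likelihood trace is non-decreasing, and tested to be), convergence
at a maximum coefficient change below 1e-8 within 100 iterations, Wald
standard errors from the observed information, OR = exp(coefficient) and
95% CI = exp(coefficient ± 1.96·SE). Complete or quasi-complete separation
(diverging coefficients, |β| > 15) and rank-deficient designs raise errors
rather than returning garbage; a non-estimable cell in an OR table is
reported with its error message while the other cells are still computed.
The single-predictor fit is verified against the closed-form 2×2 odds ratio
`ad/bc` with the Woolf interval (`or_from_2x2()`, zero cells rejected), and
the general fit against an independent reference implementation.

The OR tables are **crude** (one predictor per model) by default, mirroring
the one-row-per-predictor layout such analyses publish; whether published
tables of this kind are covariate-adjusted is often unstated, so an
`adjust = c("age", "sex")` option provides the adjusted variant without
labelling either as a reproduction. Descriptives use the pooled-variance
Student t-test (Welch is deliberately not the default, matching the named
test; a constant variable degenerates to t = 0, p = 1) and Pearson
chi-square without continuity correction.

## Pipeline, determinism and problem sizes

`run_pipeline()` composes simulate (or read a cohort CSV) → derive panel →
classify → descriptives, group means, OR tables, ROC battery, and optionally
writes each table as CSV plus `metadata.json` carrying the seed, an MD5
configuration hash and the package version. Outputs are deterministic:
identical configuration and seed give byte-identical bundles (numeric CSV
cells are printed with fixed formats; the cohort writer uses 10 decimal
places so a write/read round trip preserves values to 1e-9). The generator
saves and restores the caller's RNG state.

Default problem sizes: calibration and structural checks run at n = 50,000
— large enough that sampling error is an order of magnitude below every
tolerance they assert — and the end-to-end determinism check at n = 5,000;
unit tests use cohorts of a few hundred to a few thousand. The full suite
runs in well under a minute.

## Known limitations

* The generator's qualitative findings (stronger discrimination for
  waist-bearing indices under IDF; all scale means higher in Met-S-positive
  groups; positive scale→Met-S ORs) are structural consequences of the rule
  definitions plus a positively coupled metabolic axis; they do not validate
  the default correlation values themselves.
* Because TyG and TG/HDL are exact functions of measured TG, the crude
  component→scale odds ratio for the TG component is structurally enormous
  on synthetic data (the TG ≥ 150 component is nearly nested inside the
  high-scale flags). Comparisons of component ORs against such a component
  are not meaningful for those scales; METS-IR, where waist-linked BMI
  dominates, is the informative case.
* No insulin-based index (HOMA-IR), no LAP or VAI, no WHO/EGIR Met-S
  definitions, no survey weighting or multiple-testing correction.
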