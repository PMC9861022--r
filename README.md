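# metsynir

Surrogate insulin-resistance indices, metabolic-syndrome classification, and
the ROC / odds-ratio machinery relating them — with a calibrated synthetic
cohort generator for reproducible analysis at scale.

## The problem

Direct measures of insulin resistance (IR) — euglycaemic clamps, fasting
insulin — are unavailable in routine occupational-health and primary-care
data. Surrogate indices computed from fasting chemistry and anthropometry
are used instead, and a central epidemiological question is how well each of
them identifies subjects with metabolic syndrome (Met-S), and which Met-S
component drives the association. This package implements that analysis
end-to-end for the six indices

| Index | Definition | High-risk flag |
|---|---|---|
| TG/HDL | TG / HDL-c (mg/dL) | > 2.4 |
| TyG | ln(TG × glucose / 2) | ≥ 8.8 |
| TyG-BMI | TyG × BMI | — |
| TyG-waist | TyG × waist (cm) | — |
| TyG-WtHR | TyG × waist/height | — |
| METS-IR | ln(2·glucose + TG) × BMI / ln(HDL-c) | ≥ 50 |

and three rule-based Met-S definitions sharing the component cut-offs
TG ≥ 150 mg/dL, HDL < 40/50 mg/dL (M/F), BP ≥ 130/85 mmHg, glucose ≥ 100
mg/dL: **NCEP/ATP-III** (waist > 102/88 cm, any 3 of 5), **IDF** (waist
≥ 94/80 cm mandatory plus ≥ 2 others) and **JIS** (waist ≥ 94/80 cm, any 3
of 5). Friedewald LDL (total cholesterol − HDL − TG/5, TG < 400 mg/dL) is
included. ROC analysis reports the AUC with DeLong 95% confidence intervals
and the Youden-optimal cut-point (J = sensitivity + specificity − 1);
associations are odds ratios from binary logistic regression (IRLS, Wald
intervals).

Because subject-level data of this kind are not shared, the package ships a
seeded Gaussian-copula cohort simulator whose defaults reproduce the
sex-stratified means/SDs, age-band, smoking and social-class structure of a
large Spanish working-age population (58.8% male; men: waist 86.2 (11.1) cm,
TG 123.7 (86.4) mg/dL; women: waist 74.8 (10.6) cm, TG 89.1 (46.2) mg/dL),
with log-normal triglycerides/glucose and a positively coupled
adiposity–dyslipidaemia–dysglycaemia axis.

## Worked example

```r
library(metsynir)

report <- run_pipeline(run_config(n = 20000, seed = 42))
print(report)
#> Metabolic-syndrome / insulin-resistance analysis report
#>   cohort: 20000 subjects (58.8% male), config dd258e2a, seed 42
#>   Met-S ATPIII prevalence: 10.5%
#>   Met-S IDF    prevalence: 11.1%
#>   Met-S JIS    prevalence: 15.1%
#>   ROC battery: 36 entries (AUC range 0.767-0.964)
#>   scale->Met-S ORs: 9 fitted (range 7.20-35.55)

subset(report$roc_summary, criterion == "idf" & sex == "M",
       select = c(scale, auc, cutoff, sensitivity, specificity, youden))
#>      scale   auc cutoff sensitivity specificity youden
#>     tg_hdl 0.767   2.79       0.698       0.732  0.430
#>        tyg 0.845   8.74       0.816       0.740  0.556
#>    tyg_bmi 0.897 251.69       0.853       0.786  0.639
#>  tyg_waist 0.964 827.88       0.926       0.880  0.805
#>   tyg_wthr 0.952   4.72       0.914       0.864  0.778
#>    mets_ir 0.871  43.04       0.808       0.771  0.579
```

Each row is one index's ability to identify IDF-defined Met-S in men: its
AUC, the cut-point maximising the Youden index, and the sensitivity and
specificity at that cut-point. The waist-bearing variants (TyG-waist,
TyG-WtHR) discriminate best under IDF — the definition whose mandatory
component is elevated waist. Crude odds ratios of Met-S for high-risk index
values:

```r
subset(report$or_scale_mets, outcome == "ms_idf",
       select = c(predictor, or, or_lo, or_hi))
#>     predictor   or or_lo or_hi
#>   high_tg_hdl  7.2  6.52  7.94
#>      high_tyg 13.9 12.53 15.37
#>  high_mets_ir 11.4 10.17 12.72
```

Individual calculators are vectorised:

```r
friedewald_ldl(200, 50, 100)  # 130 mg/dL
tyg(150, 100)                 # 8.922658
mets_ir(90, 150, 30, 50)      # 44.47131
```

Cohorts round-trip through a documented CSV schema (`write_cohort()` /
`read_cohort()`), `run_pipeline()` also accepts a YAML config, and with
`out_dir=` set it writes every table as CSV plus a metadata JSON; identical
config and seed give byte-identical outputs.

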