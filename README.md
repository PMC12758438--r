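# mhquant

Automated morphometry of idiopathic full-thickness macular holes (iFTMH) on
labelled OCT B-scans, and a reproducible logistic-regression workflow for
predicting postoperative visual recovery — including *dynamic* recovery-rate
parameters derived from longitudinal follow-up.

## Who this is for

Vision scientists and ophthalmic imaging groups who already have multi-class
segmentation masks of macular-hole B-scans (from any segmenter or manual
annotation) and want:

1. **Quantitative parameters** per scan — minimum linear diameter (MLD), base
   diameter (BD), the vertical MLD–BD offset *e*, hole height, hole and
   pseudocyst areas, and ELM/EZ outer-band defect lengths;
2. **Composite indices** — MHI = height/BD, THI = height/MLD, DHI = MLD/BD,
   and the hole-to-pseudocyst area ratio;
3. **Qualitative flags** — ERM presence and a tractional space;
4. **Dynamic parameters** — for each lesion (hole area, pseudocyst area,
   ELM/EZ defect length) over the five-visit schedule *pre, 2 wk, 3 mo, 6 mo,
   12 mo*, the resolution time t (first visit observed at zero) and the
   recovery rate

   rate = initial size / t,

   optionally shape-weighted by the inverse circularity
   φ = P²/(4πA) of the preoperative lesion:
   rate_w = rate · (1 + κ(φ − 1)), κ = 0.5 by default.
   Censored (never-resolved) lesions get the mean-shrinkage fallback
   (initial − last)/t_last in the default `extended` mode, or a missing rate
   in strict `paper` mode;
5. **Prognosis models** — ETDRS letter gain ≥ 20 defines *superior* recovery;
   the workflow runs mean imputation (strict <10 % missingness rule),
   Shapiro–Wilk–guided Pearson/Spearman correlation, iterative VIF filtering
   (threshold 5), univariate logistic screening (P < 0.10), an in-package
   IRLS logistic fit with Wald inference (OR = exp(B),
   CI = exp(B ± 1.96·SE)), Nagelkerke R², and a seeded, stratified 8:2
   split with 5-fold CV comparing models **with vs without** the dynamic
   parameters (ΔAUC);
6. **Segmentation metrics** — per-class Dice, IoU, accuracy, F1 and pixel
   ROC AUC for benchmarking any external segmenter against reference masks.

A seeded phantom generator (`simulate_cohort()`) renders whole longitudinal
cohorts — masks, clinical tables, outcomes — with ground truth known by
construction, so the entire pipeline is testable offline with no data
download.

## Worked example

```r
library(mhquant)

co   <- simulate_cohort(phantom_params(n_eyes = 200, seed = 1))
head(co$features[co$features$eye_id == "eye0001",
                 c("stage","mld_um","bd_um","height_um","mh_area_um2",
                   "ez_defect_um","mhi")], 5)
#>   stage mld_um bd_um height_um mh_area_um2 ez_defect_um    mhi
#> 1   pre 186.25 466.3     383.3      125084        620.3 0.8220
#> 2   wk2 132.77 324.9     271.6       62158        436.6 0.8361
#> 3   mo3  89.59 227.8     188.7       29949        304.5 0.8283
#> 4   mo6     NA    NA        NA           0        208.9     NA
#> 5  mo12     NA    NA        NA           0          0.0     NA
```

This eye's hole shrinks over two visits and is closed (`mh_area_um2 = 0`,
hole geometry missing) from month 6; its EZ defect closes by month 12.

```r
dyn <- compute_dynamics(co$features)
head(dyn[c("eye_id","t_resolved_mh","rate_mh","t_resolved_ez","rate_pct_ez")], 3)
#>    eye_id t_resolved_mh rate_mh t_resolved_ez rate_pct_ez
#> 1 eye0001            26    4811            52       1.923
#> 2 eye0002            13    7930            13       7.692
#> 3 eye0003            52    4055            52       1.923
```

`rate_mh` is µm²/week of hole closure; `rate_pct_ez` is the percent of the
initial EZ defect recovered per week (100/t when resolved).

```r
cmp <- compare_with_without_dynamics(co$features, dyn, co$clinical,
                                     stage = "mo3", seed = 1)
#> test AUC with dynamics 0.698 vs without 0.534 (delta +0.164)
cmp$with_dynamics$report
#> <model_report> n = 155, Nagelkerke R2 = 0.294, AUC = 0.779
#>           term      B    SE   wald     p     or ci_lo  ci_hi
#>    (Intercept)  2.690 0.865  9.669 0.002 14.725 2.703 80.225
#>  duration_days -0.013 0.004  8.290 0.004  0.987 0.979  0.996
#>   ez_defect_um -0.003 0.001 10.413 0.001  0.997 0.995  0.999
#>        rate_mh  0.000 0.000  0.784 0.376  1.000 1.000  1.000
#>   rate_pct_elm  0.021 0.021  1.055 0.304  1.022 0.981  1.064
#>    rate_pct_ez  0.014 0.019  0.570 0.450  1.014 0.978  1.052
```

The report rows are the standard logistic summary: coefficient B, S.E.,
Wald statistic, P, odds ratio Exp(B) and its 95 % CI. `interpret_or(0.968)`
turns an odds ratio into the clinical phrasing ("decreased by approximately
3.2%").

## Command line

```sh
Rscript inst/cli/mhquant.R simulate --out cohort --seed 7 --n 60 --render
Rscript inst/cli/mhquant.R quantify --masks cohort/masks --out features.csv
Rscript inst/cli/mhquant.R dynamics --features features.csv --out dynamics.csv
Rscript inst/cli/mhquant.R compare  --features features.csv --dynamics dynamics.csv \
        --clinical cohort/clinical.csv --stage mo3 --seed 1 --out report.json
Rscript inst/cli/mhquant.R seg-metrics --pred predmasks --ref refmasks --out seg.csv
Rscript inst/cli/mhquant.R report --config pipeline.yaml   # full pipeline
```

Masks are 8-bit single-channel PNGs of label codes (0 background,
1 macular hole, 2 pseudocyst, 3 ERM, 4 space, 5 VMT, 6 PVD, 7 ELM, 8 EZ,
9 RPE) with a JSON sidecar carrying `eye_id`, `stage`, `axis` and
`spacing_um` (axial, lateral µm/px).

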