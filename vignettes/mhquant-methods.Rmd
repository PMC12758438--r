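---
title: "Measurement conventions, dynamic parameters, and the phantom world of mhquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement conventions, dynamic parameters, and the phantom world of mhquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhquant)
```

## The problem

After surgical repair of an idiopathic full-thickness macular hole (iFTMH),
anatomical closure is common but functional recovery varies widely. Static
preoperative OCT measurements — hole diameters, height, outer-band
integrity — predict visual outcome only partially. `mhquant` quantifies
those static parameters automatically from multi-class segmentation masks
and adds *dynamic* descriptors of how fast each lesion resolves across the
five-visit follow-up grid, then asks, with a fully specified statistical
protocol, whether those dynamics add predictive value for a binary
visual-recovery outcome (an ETDRS letter gain of at least 20).

The package consumes masks; it does not segment. Any segmenter (or manual
annotation) that emits the ten-code label schema can feed it.

## Measurement conventions

All grids are oriented with row 1 at the vitreous side; columns are the
lateral direction. A pixel's physical size is `spacing_um = (axial,
lateral)` µm, which is mandatory input metadata (public OCT exports rarely
embed trustworthy spacing, so the JSON sidecar is the source of truth).

**Hole geometry.** Only the largest 8-connected hole component is measured;
stray annotation islands are discarded with a message. Per-row widths are
lateral *extents* — the span from first to last hole pixel — so interior
islands (operculum remnants) never shrink a width; this matches how a
clinician places callipers on the display. BD is the width of the
bottommost hole row, MLD the minimum row width with ties broken toward the
base row (making the MLD–BD offset *e* deterministic), height the inclusive
row extent, and area the component pixel count times the pixel area.
Column spans convert to µm as `(max − min + 1) × lateral spacing`. MLD is
measured strictly horizontally, not parallel to the RPE — an explicit
convention users should be aware of when comparing against oblique-calliper
readings.

**Band defects.** An ELM or EZ defect is the largest run of absent columns
strictly inside the band's lateral footprint (`mode = "sum"` totals all
gaps instead; the largest single gap is the default because one foveal
disruption is the clinical object). A contiguous band has defect 0; a band
with no pixels at all yields a *missing* defect — absence of evidence about
the band is not a zero-length defect. Region areas, by contrast, are
legitimately zero when the label is absent.

**Qualitative flags.** ERM and tractional-space presence use a pixel-count
threshold (default 20 px) to suppress annotation speckle; no published rule
exists, so the threshold is exposed in the configuration.

**Visit aggregation.** Each examination contributes a horizontal and a
vertical B-scan. Sizes aggregate by arithmetic mean over the scans on which
they are measurable, flags by logical OR, and the composite indices (MHI,
THI, DHI, hole/pseudocyst area ratio) are recomputed from the aggregated
primitives rather than averaged per scan — the ratio-of-means choice makes
the identity DHI × THI = MHI hold exactly and keeps every reported index
auditable from the reported primitives. How the two axes *should* be merged
is genuinely unspecified in the source protocol; mean/min/max are all
available.

## Dynamic parameters

The visit schedule maps stages to weeks: pre = 0, 2 weeks = 2, and months
3/6/12 = 13/26/52 (integer weeks; a per-month unit is available by dividing
rates by 4.345). For each lesion — hole area, pseudocyst area, ELM and EZ
defect length — the resolution time is the **first** postoperative visit
observed at exactly zero. A nonzero after a zero (recurrence) still
resolves at the first zero, with a warning, never silently. A lesion absent
preoperatively has *undefined* dynamics (missing, not zero).

The recovery rate is `initial size / t_resolved`. Two censoring modes
exist: strict `paper` mode leaves never-resolved lesions without a rate;
the default `extended` mode reports the mean shrinkage rate
`(initial − last)/t_last` so that prognostic models need not drop censored
eyes. Band-defect rates are additionally emitted on a percent scale
(`100 × rate / initial` = percent of the initial defect recovered per
week), since per-percentage-point odds ratios are the natural clinical
reading for band integrity.

**Shape weighting — a reconstruction.** The source protocol names a
"shape-weighted factor" for pre-resolution morphological complexity but
does not specify it. `mhquant`'s reconstruction — chosen once, documented,
and config-exposed — is the inverse circularity φ = P²/(4πA) of the largest
preoperative component, with the perimeter taken from the 0.5-level
marching-squares contour (sub-pixel, so a rasterised disc measures
φ ≈ 1.05–1.13 rather than the ≈1.62 a naive pixel-edge count gives; a
square tends to 4/π). The adjustment is linear:
`rate_w = rate × (1 + κ(φ − 1))`, κ = 0.5, which is the identity for
circular lesions and non-decreasing in both φ and κ. These are this
package's choices, not the original authors'; any downstream use should
say so.

## The outcome protocol

Superior recovery at a stage means ETDRS(stage) − ETDRS(pre) ≥ 20
(boundary inclusive); a missing ETDRS at either end propagates to a
missing label. Preprocessing is deliberately rigid so the trail is
reproducible:

* numeric columns with missing fraction strictly below 10 % are
  mean-imputed, others dropped (9.99 % imputes, 10.0 % drops), both sets
  reported;
* Shapiro–Wilk at α = 0.05 on each variable and on the outcome decides
  Pearson vs Spearman correlation;
* VIF = 1/(1 − R²) is recomputed after each single worst-predictor
  removal until all VIF ≤ 5 (exact collinearity loses exactly one copy);
* univariate logistic screening retains predictors with Wald P < 0.10,
  with no multiplicity correction (matching the source protocol; the
  acceptance suite verifies the 10 % null retention rate);
* the final fit is an in-package IRLS maximum-likelihood logistic
  regression (log-likelihood tolerance 1e-8, max 100 iterations,
  step-halving for monotonicity, SEs from the inverse observed
  information). Odds ratios are exp(B) with fixed-multiplier 1.96 Wald
  CIs — profile likelihood is deliberately out of scope because the
  published coefficient arithmetic is the Wald form. Nagelkerke
  R² = (1 − exp((2/n)(ℓ₀ − ℓ₁))) / (1 − exp((2/n)ℓ₀));
* discrimination: rank (Mann–Whitney) AUC with midrank ties — proven equal
  to the brute-force pairwise count in the test suite — plus step-summed
  AUPRC and accuracy/sensitivity/specificity at threshold 0.5 (the source
  threshold is unstated; 0.5 is the neutral default);
* the with/without-dynamics comparison uses a seeded stratified 8:2 split
  and stratified 5-fold CV on the training set, the *same* split and folds
  in both arms, so ΔAUC is exactly 0 when the predictor sets coincide.
  Stratification is a package choice (the source states only "8:2" and
  "5-fold") to keep the minority class represented; the fold count is
  reduced with a warning when a fold would lack minority cases.

Note one inherent property carried over from the source design: dynamic
parameters are computed from the full follow-up series, so models of early
outcomes that include them are descriptive of association, not real-time
forecasts.

## The phantom world

`simulate_cohort()` states its world once (all defaults overridable):

* geometry: BD ~ U(300, 900) µm, DHI ~ U(0.3, 0.7), height ~ U(250, 450)
  µm, trapezoidal hole profile (base BD on the RPE, top MLD) — chosen
  because MLD/BD/height/e/area are analytically known at pixel level, so
  generator–extractor agreement can be asserted *exactly*;
* band defects proportional to BD (EZ ×1.3, ELM ×1.15, ±30 µm noise),
  clamped to exceed the hole width where the hole crosses the band —
  a full-thickness hole cannot leave an intact outer band narrower than
  itself;
* healing: a per-eye latent score plus per-lesion jitter maps to
  resolution stages with marginal probabilities wk2 .25, mo3 .35, mo6 .20,
  mo12 .10, never .10; band restoration never precedes hole closure;
  sizes shrink geometrically (linear dims ×0.7 per visit, pseudocyst area
  ×0.5) and hit exactly zero at the resolution stage;
* clinical covariates: age ~ N(68, 8), symptom duration ~
  LogNormal(log 60, 0.6) days, ETDRS_pre ~ U(25, 60), 5 % postoperative
  ETDRS missingness;
* outcome: P(superior) = logistic(0.3 + offset_stage − 0.8·z_BD −
  0.5·z_dur + 0.8·z_EZrate + 0.4·z_MHrate) on fixed-scale standardised
  true features (log scales for the rates, whose distributions are
  heavy-tailed by construction); the ETDRS letter gain is then drawn with
  a 1–15 letter margin away from the 20-letter boundary, so label
  round-tripping is never decided by an off-by-one;
* rendering: each stage draws the horizontal and vertical scan with
  independent N(0, 5 µm) geometric jitter; the recorded per-visit truth is
  the mean of the two *rendered* (pixel-quantised) truths, mirroring the
  feature aggregation rule. Truth-level cohorts (`render = FALSE`) skip
  rasterisation and instead add N(0, 3 µm) observation noise to nonzero
  sizes — exact zeros stay exact, because resolution detection is a
  first-zero rule.

What the phantoms do **not** emulate: OCT speckle or any intensity
content, curved retinal anatomy, oblique holes, segmentation errors,
annotation disagreement, visit-schedule irregularity, or correlated
bilateral eyes. A green generator–extractor test therefore establishes the
*measurement* chain, not robustness to imperfect segmentation; the
segmentation-metrics module exists precisely so external segmenters can be
benchmarked before their masks are trusted.

## Numerical choices and degenerate inputs

* Tie-breaks: MLD ties go to the base-most row; AUC ties use midranks;
  the VIF loop drops exactly one predictor per iteration.
* A 1-pixel hole measures mld = bd = one lateral spacing, height = one
  axial spacing, e = 0.
* A present hole with zero MLD or BD is a hard error (degenerate
  annotation), as is any mask value outside the schema.
* IRLS non-convergence raises an error carrying the log-likelihood trace;
  complete separation warns and flags the report (screening keeps such
  predictors but marks their P unreliable).
* Heavy acceptance suites (coefficient-recovery coverage over 200 cohorts
  of n = 2000; the 100-run ΔAUC comparison) run on truth-level cohorts:
  rendering ~4 million B-scans is neither feasible on one CPU nor
  informative, since rendering fidelity is pinned down separately by the
  200-phantom exact round-trip.

## Known limitations

* Dynamics are visit-grid rates; no continuous-time healing-curve fitting.
* MLD is horizontal by convention; oblique measurement is out of scope.
* Pixel ROC AUC on hard masks degenerates to (sensitivity +
  specificity)/2 and is flagged as such; only probability maps give the
  full rank AUC.
* The shape-weighting functional form is a documented reconstruction, not
  a published formula.
* The outcome threshold (20 letters) and every protocol constant are
  config-exposed, but the defaults are the validated path.
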