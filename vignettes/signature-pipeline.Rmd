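---
title: "Methods: AD brain signatures and 12-year MCI risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AD brain signatures and 12-year MCI risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsignatures)
```

## Scientific background

This package implements an analysis pipeline for composite Alzheimer's
disease (AD) neuroimaging *signatures* in a longitudinal twin cohort of
middle-aged men, and their use to predict progression from cognitively
normal (CN) status to mild cognitive impairment (MCI) roughly twelve years
later. Two signatures share one fixed set of eight bilateral regions of
interest (entorhinal, middle temporal, banks of the superior temporal
sulcus, superior temporal, isthmus cingulate, lateral and medial
orbitofrontal cortex, hippocampus) and one fixed set of sixteen
region-by-hemisphere weights derived in an independent case-control sample
(`signature_weights()`; the weights sum to 7.044):

* the **thickness/volume signature** combines cortical thickness for the
  seven cortical regions with hippocampal volume (lower = more AD-like);
* the **MD signature** combines grey-matter mean diffusivity (MD) for the
  same sixteen ROIs (higher = more AD-like).

Because restricted cohort data cannot ship with the package, a calibrated
synthetic twin-cohort generator (`generate_cohort()`) provides data with
the statistical structure the pipeline assumes, with known ground truth for
every quantity the pipeline estimates.

## Grey-matter MD reconstruction

Cortical MD is sampled seven times along the surface normal (0.8-2.0 mm in
0.2 mm steps). Each sample is weighted by a Tukey bisquare function of the
grey-matter volume fraction `v` of its voxel,
`w(v) = (1 - ((1 - v)/t)^2)^2` for `1 - v < t` (else 0), with `t = 0.5`
(`fraction_weight()`): voxels at most half grey matter are excluded
entirely, and the weight rises smoothly to 1 for pure grey matter. This
suppresses CSF and white-matter partial-volume contamination
(`cortical_vertex_md()`). Subcortical ROIs instead downweight voxels far
from the ROI median relative to 4.7 times a typical dispersion (the
across-subject-averaged median absolute deviation), again with a bisquare
kernel (`subcortical_roi_md()`).

`generate_md_phantom()` builds noise-free voxel phantoms whose rim voxels
mix grey matter with CSF or white matter at fractions of at most 0.5. By
construction the fraction-weighted estimator recovers the true grey-matter
MD *exactly* while the unweighted mean is biased; the test suite asserts
this gap. **Limitation:** real partial-volume voxels can be grey-matter
dominant (fraction above 0.5); such voxels receive positive weight and
would bias even the weighted estimator. The exact-recovery property is a
property of the phantom's construction, not a general guarantee.

## Signature scoring

At each wave, every ROI measure is residualized by ordinary least squares
on age and scanner (plus estimated intracranial volume for hippocampal
volume only), and the residuals are standardized (`residualize_roi()`).
The covariate models are fit on the full wave sample rather than a
CN-only subsample so that scoring does not depend on diagnosis. The
sixteen standardized residuals are combined with the published weights
(`composite_score()`) and the composite is z-scored within wave
(`score_signatures()`); per-wave standardization makes the raw weighting
scale irrelevant and renders scores invariant to per-ROI unit changes.

The predicted brain age difference (PBAD) is chronological age minus
predicted brain age; more negative values indicate an older-looking brain.
`pbad_adjust()` residualizes scores on PBAD per wave and modality and
re-standardizes, producing signature variants orthogonal to the global
brain-age gap.

## Actuarial diagnosis with practice/attrition correction

Cognition is an 18-test battery over six domains (memory, executive,
attention, language, visuospatial, processing speed) on a normative z
scale. Before diagnosis:

1. **GCA adjustment** (`gca_adjust()`): each test is adjusted for general
   cognitive ability measured around age 20 by removing the fitted GCA
   slope while keeping level and scale (scores at the sample-mean GCA are
   unchanged, and residual spread is *not* re-inflated). This prevents
   lifelong-low-ability individuals from being over-flagged; re-inflating
   the residuals would put borderline subjects back near the cutoff and
   raise the false-positive rate, so the level-preserving form is used.
2. **Replacement-subjects correction** (`estimate_adjustments()`,
   `apply_adjustments()`): for each test and wave, the attrition effect is
   the mean prior-wave score of returnees minus that of all prior-wave
   participants, and the practice effect is the returnee-minus-replacement
   current-wave difference minus the attrition effect. The estimated
   practice effect is subtracted from returnees' scores.

Diagnosis follows the Jak-Bondi actuarial rule (`classify_wave()`): a
domain is impaired when at least two of its tests fall strictly below
-1.5 SD; MCI means at least one impaired domain. Longitudinal status
(`longitudinal_status()`) labels subjects robust-CN (CN at every attended
wave), converter (CN at wave 1, MCI at the final wave), MCI, or excluded
reverter (any MCI-to-CN transition; removed from analyses).

## Statistical models

* **Concurrent comparisons** (`fit_concurrent_lmm()`,
  `concurrent_analysis()`): signature score on group, wave, and their
  interaction, with random intercepts for twin pair and subject;
  Satterthwaite degrees of freedom; when the interaction is not
  significant the main-effects model is reported. The standardized mean
  difference is the adjusted group coefficient over the pooled raw SD.
* **Risk prediction** (`fit_risk_model()`): mixed-effects logistic models
  of conversion on z-scored predictors with a pair random intercept.
  Model 1 uses age + AD polygenic risk score (PRS); Models 2-4 add the
  thickness/volume and/or MD signatures; Model 5 uses the PBAD-adjusted
  signatures. Fitted probabilities use fixed effects only.
* **ROC analysis** (`roc_auc()`, `youden_threshold()`, `roc_report()`):
  midrank Mann-Whitney AUC, Youden-optimal threshold (ties broken toward
  higher specificity), stratified-bootstrap percentile CI.
* **Model comparison** (`bootstrap_auc_compare()`): cases and controls are
  resampled separately, the AUC difference is recomputed per replicate,
  and the observed difference divided by the bootstrap SD is referred to a
  standard normal. Its type-I calibration is verified by simulation in the
  acceptance suite.
* **Multiplicity** (`fdr_bh()`): Benjamini-Hochberg FDR at 0.05, applied
  separately to the concurrent family and the predictive-comparison
  family.

## Design of the synthetic generator

`generate_cohort()` is the package's replacement for restricted cohort
data; every design choice below is aimed at making the pipeline's
estimators identifiable and testable.

**Twin structure.** All subject-level latent traits are *pair-correlated
standard normals*: `sqrt(rho)` times a pair component plus `sqrt(1-rho)`
times an individual component, with `rho` equal to the configured ICC for
MZ pairs and a configurable share of it (default one half) for DZ pairs.
Every trait therefore has exactly the configured within-pair correlation,
which the tests verify by double-entry ICC at `n_pairs = 5000`.

**ROI model.** Each of the 16 ROI-by-hemisphere measures per modality is
`sqrt(0.4) F + sqrt(0.3) U + sqrt(0.3) E` in standardized units: a
per-modality common factor `F` (wave-specific), a persistent ROI-specific
component `U`, and transient wave noise `E`. The two modality factors
share a wave-specific "brain health" factor with opposite signs, with a
coupling share rising across waves (defaults 0.30/0.475/0.65); this
produces the negative and strengthening thickness/volume-MD score
correlation across waves (about -0.28/-0.45/-0.60) without building in any
converter effect.

**Analytic effect calibration.** Converters' ROI measures are shifted by a
constant `delta` per ROI (positive for MD, negative for
thickness/volume). Because the signature is a weighted sum of
standardized residuals that is z-scored per wave, the signature-level SMD
induced by a per-ROI shift `delta` is available in closed form: with
weights `w` and common-factor share 0.4, the signature variance is
`0.4 (sum w)^2 + 0.6 sum(w^2)`, so
`delta = SMD * sqrt(0.4 (sum w)^2 + 0.6 sum(w^2)) / sum(w)`. The
generator inverts this exactly rather than calibrating by pilot
simulation. The shift is constant across waves, consistent with the
absence of a group-by-wave interaction in the concurrent models.

**Cognition.** Test scores are `g + d + 0.45 e` plus structural terms,
where `g` (SD 0.7) is general ability, `d` (SD 0.25) a persistent domain
effect, and `e` per-test transient noise. The transient SD 0.45 puts
test-retest reliability near 0.74, in the 0.7-0.8 range typical of
neuropsychological tests, and keeps the actuarial classifier's
chance-impairment floor small so the realized converter fraction tracks
the configured latent rate. Age-20 GCA is `g` plus independent noise.
Converters decline only at the final wave: 3.0 SD on memory tests and
0.6 SD elsewhere, so detection is near-certain and conversion is not
visible at earlier waves.

**Practice, attrition and replacements.** Returnees gain a flat 0.15 SD
practice effect. Dropout is confined to a latent *frail* subgroup (35% of
subjects) who carry a persistent -0.2 SD deficit; frail subjects drop out
at `0.12 / 0.35` per transition, so the marginal dropout rate is 12% and
future dropouts have exactly the configured pre-dropout deficit, while
fresh replacement pairs (16% of baseline pairs per later wave, drawn from
the same population, including frailty and conversion eligibility) stay
representative. This makes the replacement-subjects estimator consistent:
at `n_pairs = 5000` the recovered practice effect is within 0.03 SD of
the injected 0.15.

**Conversion.** Latent conversion is Bernoulli with probability from a
logistic in standardized baseline age and PRS (log-odds 0.35 and 0.25);
the intercept is solved numerically so the marginal rate equals the
configured 11.8%.

**PBAD.** The brain-age gap loads on the shared health factor, so worse
signatures accompany older-looking brains; PBAD adjustment therefore
removes real shared variance rather than pure noise.

## Problem sizes and runtimes

Default analyses use `n_pairs = 2000` (about 5,400 subjects including
replacements; the wave-1 CN predictive sample is about 3,100).
Calibration checks use `n_pairs = 5000`. Generation takes about a second
at `n_pairs = 5000`; a full `run_pipeline()` at `n_pairs = 2000` with
1,000 bootstrap replicates runs in a few minutes on one core.

## Reproducing the analyses

```r
cfg <- cohort_config(seed = 1, n_pairs = 2000)
res <- run_pipeline(cfg, out_dir = "artifacts", n_boot = 2000)
print(res)
```

Re-running with the same configuration reuses cached stage artifacts; the
manifest in `artifacts/manifest.json` records configuration and file
digests. The acceptance report is generated by
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`.
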