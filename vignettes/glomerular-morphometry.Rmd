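---
title: "Glomerular morphometry on kidney sections: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glomerular morphometry on kidney sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Autopsy kidney sections offer something in-vivo biopsies cannot: hundreds
of glomerular profiles per individual, enough to estimate glomerular
density and size reliably. The analysis chain this package implements
takes an H&E-stained section image through three classification stages —
background vs tissue, cortex vs medulla, and glomerulus detection within
the cortex — then converts the detected profiles into stereological
quantities and cohort-level statistics.

Glomerular density (GD) is the number of glomerular profiles per mm² of
cortical section. Mean glomerular volume follows the Weibel–Gomez
estimator

$$ GV = \frac{1.382 \cdot \bar A^{3/2}}{1.01} $$

with $\bar A$ the mean profile area (µm², converted to mm³), 1.382 the
shape coefficient for spheres sectioned at random and 1.01 a
size-distribution correction. The volumetric glomerular density is

$$ VGD = \frac{1}{1.382} \sqrt{\frac{(N/A)^3}{S/A}} $$

with $N$ the profile count, $A$ the cortex area and $S$ the summed
profile area. These two estimators are algebraically linked: when $GV$
uses $\bar A = S/N$,

$$ VGD \cdot GV = \frac{S/A}{1.01}, $$

i.e. their product is the areal fraction of cortex occupied by glomeruli
divided by the size correction. The test suite asserts this identity to
$10^{-12}$ relative error; it is a strong internal-consistency check on
the unit conversions (object areas are carried in µm², cortex areas in
mm², with a single conversion constant of $10^6$).

A note on magnitudes: evaluating the VGD equation at a typical cohort
(GD ≈ 2.23 mm⁻², areal fraction ≈ 0.054) gives roughly 10–11 mm⁻³.
Published cohort VGD figures of ~18 mm⁻³ alongside the same equation are
about 1.8× larger than the equation yields at the cohort's own mean
inputs; the package implements the equation exactly as written and makes
no attempt to reconcile that gap.

## The detector

Commercial deep-learning classifiers are not reproducible from their
published descriptions, so the detector here is a deterministic,
fully-documented classical operator chain standing behind the same
interface (a substitute learned model could be slotted in). All features
are derived from per-channel optical density $OD_c = -\log I_c$, because
ratios of optical densities are invariant to a global staining-intensity
multiplier — the property that makes the pipeline stable across slides
stained weakly or strongly.

1. **Tissue vs background.** Chromatic saturation of the smoothed image
   (10 µm scale). Stained tissue is pink/purple at every intensity;
   background is neutral. The threshold adapts per slide (Otsu on the
   saturation map) with an absolute floor of 0.03 and a cap at half the
   upper-mode mean so that a slide that is entirely tissue is not split.
   Enclosed holes under 1,000 µm² are filled.
2. **Cortex vs medulla.** Local mean total absorbance, smoothed over
   30 µm *within* the tissue mask (normalized convolution, so background
   cannot bleed in). Cortex stains denser than the tubule-dominated
   medulla. Otsu's threshold separates the two modes after clipping the
   field at 1.3× its 75th percentile (which removes the glomerular-tuft
   spike); a medulla is only declared when both modes carry at least 8%
   of the tissue and differ by at least 12% — otherwise the slide is
   labeled all-cortex. The medulla mask is cleaned by opening/closing at
   18 µm and dropping fragments under 0.05 mm².
3. **Glomerulus detection.** A tuft pixel must satisfy two stain-ratio
   criteria: $OD_R/OD_G > 0.5$ (the hematoxylin-rich tuft is blue-purple
   against pink cortex, whose ratio is ≈ 0.3) and $OD_G$ above 1.35× the
   cortex median (absolute depth, expressed relatively so it survives
   staining changes). Candidate components are 8-connected; holes under
   2,000 µm² are filled; components under the 40 µm² detection floor are
   discarded at this stage, and objects whose centroid falls outside the
   cortex are flagged rather than silently dropped. A post-hoc cleaning
   filter excludes objects under 10,000 µm² — the strict inequality is
   deliberate: an object of exactly 10,000 µm² is kept. Objects touching
   the image border are kept but carry an `on_border` flag.

Per-object area is pixel count × mpp²; perimeter uses a four-direction
Cauchy–Crofton estimate, $P = (\pi h/8)(X_0 + X_{90} +
(X_{45}+X_{135})/\sqrt2)$ over scan-line transition counts. Tests verify
its bias is below 3% for ellipses at or above the 10,000 µm² cleaning
floor rendered at 2 µm/px (measured: under 0.5%). Component labeling is
an in-package run-merging union-find because the imaging library's
labeling is 4-connected only.

Resolution is standardized to 2 µm/px before measurement: exact block
averaging for integer factors, antialiased bilinear resampling
otherwise; only downsampling is supported since upsampling fabricates
detail.

There is no randomness anywhere in segmentation: identical pixels give
identical results.

## The synthetic slide and cohort generator

No autopsy material ships with the package, so a generator produces
slides with exact ground truth. Its defaults *are* the study conditions
the analysis assumes; they were fixed once from the cohort the pipeline
emulates and are not tuning knobs:

* planted glomerular density 2.23 ± 0.52 per mm² across individuals;
* mean tuft cross-section 24,337 µm² with SD 5,775 µm² (the N-weighted
  mean of the published per-sex cohort values), truncated to
  [12,000, 38,000] µm² — the upper cut at about mean + 2.4 SD keeps
  draws inside the observed cohort range and keeps capsules placeable;
  per-glomerulus draws on a slide are truncated below at 10,500 µm² so
  every planted object survives the 10,000 µm² cleaning filter;
* a planted density–area correlation of −0.59 (sampled as a conditional
  normal so both marginals are preserved), giving the cohort statistics
  a real signal to find;
* four staining levels implemented as global absorbance multipliers
  (0.55, 0.80, 1.00, 1.35) of a fixed H&E-like palette — intensity
  varies, hue structure does not;
* left/right within-subject jitter of SD 0.15 mm⁻² in density and
  500 µm² in area (small relative to between-subject spread, matching
  the near-equality of published left/right kidney summaries).

Geometry is sampled in physical units (microns) *before* rasterization:
the section is an ellipse filling 92% of the frame, the medulla an inner
region bounded by a low-order harmonic perturbation of a concentric
ellipse, and glomeruli are ellipses with axis ratio uniform on
[0.75, 1], random orientation, a dark mottled tuft and a pale Bowman rim
at 1.10× the tuft axes. Placement is rejection sampling: the whole
capsule outline must fall in cortex and centres must be at least 1.5×
the mean diameter apart (real glomeruli do not touch), with 1,000
retries before the generator refuses the density as infeasible for the
geometry. Because geometry precedes rasterization, one sampled slide can
be rendered at several resolutions or staining levels with *identical*
ground truth — this is how the resolution- and stain-invariance
properties are tested. The planted count is exactly
round(GD × cortex area), with cortex area computed analytically by
quadrature over the harmonic boundary.

Subject covariates are truncated normals with the per-sex means, SDs and
ranges of the emulated cohort (54 men, 32 women); BMI is derived from
height and weight, BSA by Du Bois (0.007184 · h^0.725 · w^0.425, the
common choice in European clinical studies). One deliberate
re-interpretation: the source table prints kidney weight as 161.1 ± 5.5 g
(men) and 127.5 ± 4.6 g (women); dispersions that small are not
plausible as SDs and contradict the same cohort's median-split table
(SDs ≈ 44/30 g), so they are read as standard errors and converted
(SE·√n ≈ 40.4 and 26.0 g), which reproduces the median-split table's
spread. Covariates are drawn independently of each other (the joint
distribution is unpublished); recovery tests therefore compare empirical
moments against *truncated*-normal references, not the untruncated
parameters.

What the generator does **not** emulate: nuclei-level texture, sclerotic
or partly sclerotic glomeruli (the emulated workflow counts only intact
ones), stain batch hue shifts, scanner artefacts, tissue folds and
out-of-focus regions. Passing tests therefore demonstrate that the
measurement chain is correct and calibrated on well-formed sections, not
that the classical detector would match a trained network on real
histology — on real slides the detector interface is the intended
substitution point.

## The eligibility filter

A record is eligible iff every exclusion flag is false and age ≥ 18.
Exclusion reasons are attributed to the *first* triggered flag in the
fixed order kidney_disease, trauma, putrefaction, drug_toxicity,
blood_depletion, minor, mutilated, so the per-reason partition is
deterministic even for multi-flag records. The intake simulator plants a
configurable number of flagged records (default 1165 → 86) with a fixed
plausibility mix and a 20% second-flag rate.

## Statistics

* **Normality gate:** Shapiro–Wilk p ≥ 0.05 AND |sample skewness| < 1.
  The published analysis names both checks without stating how they
  combine; the AND rule is the conservative documented choice. Constant
  samples fail the gate and are flagged degenerate.
* **Two-group comparison:** Welch's t when both groups pass the gate,
  Wilcoxon rank-sum otherwise. Welch rather than pooled-variance t
  because the group sizes differ (54 vs 32) and equal variances buy
  nothing. Under a normal null at these sizes the gated procedure's
  type-I error is ≈ 0.048 (10,000 replicates in the acceptance run).
* **Chi-squared:** Pearson, no continuity correction.
* **Median split:** low group takes values ≤ median (ties go low; the
  published table headers use strict inequalities and are silent on
  ties).
* **Regression strategy:** per-covariate OLS screen; covariates with
  univariate p < 0.05 enter one multivariable model; if the full model's
  residuals fail Shapiro–Wilk at 0.05 and the outcome is strictly
  positive, the outcome is log-transformed and the model refit.
  Collinear candidate sets (pairwise |r| > 0.999 or condition number
  above 10⁸) are refused with the offending pair named.
* No multiple-testing adjustment, matching the emulated analysis plan
  (α = 0.05 throughout).
* **Median confidence interval:** 95% order-statistic (binomial)
  interval — the emulated analysis reports a median CI without naming a
  method; this is the standard distribution-free choice.
* **Validation rates:** false positives and false negatives are both
  expressed as percentages of the *reference* (manual) count, the
  convention used when an algorithm is audited against an observer;
  precision/recall are exported alongside. The point-reference match
  radius defaults to √(10,000/π) ≈ 56 µm, the radius of the smallest
  keepable glomerulus, tying the matching tolerance to the pipeline's
  own size floor. Matching is greedy by centroid distance over eligible
  pairs; tests confirm it equals exhaustive optimal assignment on
  spaced, jittered configurations.

## Problem sizes and numerical choices

The test and acceptance runs use slides of 1200 × 900 px at 2 µm/px
(2.4 × 1.8 mm, ≈ 1.6 mm² of cortex, 3–5 glomeruli each) and a 20-slide
recovery cohort; the smaller unit-test fixture is 800 × 600 px with a
cortex-heavy profile. These sizes were chosen so that each slide carries
a meaningful cortex band and several well-separated capsules while a
full suite run stays in the minutes range; nothing in the method depends
on slide size, and the generator accepts arbitrary dimensions. Replicate
counts follow the stated calibration design: 10,000 null replicates for
the type-I error of the gated comparison, 1,000 for regression CI
coverage.

Degenerate inputs are handled explicitly rather than by accident: a
slide with no tissue returns an empty mask with a warning; an
all-cortex slide yields zero medulla (the mode-separation guard); zero
detected glomeruli yield GD 0 with size statistics as flagged missing
values (never 0, which would corrupt cohort means); glomeruli reported
against a zero-area cortex raise an error.

## Reproducibility

Every stochastic component is a pure function of (parameters, seed):
generating the same spec twice is bit-identical, and a pipeline rerun
with the same config and seed reproduces the metrics CSVs byte for
byte (the run directory carries an md5 manifest and a stage-by-stage
log). Numeric CSV columns are written at full precision (%.17g) so
write-read round trips are exact.

## Known limitations

* The classical detector is tuned to the generator's H&E palette family;
  real-world stain variability beyond a global intensity factor (hue
  shifts, batch effects) is out of scope.
* GD is a proxy for nephron endowment, not a nephron count; without
  cortical volume no total nephron number can be derived, and none is
  reported.
* Sclerotic glomeruli are neither modeled nor classified.
* The VGD equation's printed-vs-evaluated magnitude gap (above) is
  documented, not resolved.
* The age-matched subgroup analysis of the emulated study has no stated
  construction method and is not implemented.
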