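---
title: "Striatal SBR quantification, phantom harmonization and normative modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striatal SBR quantification, phantom harmonization and normative modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbrnorm)
```

## The problem

Dopamine-transporter (DAT) SPECT with [123I]FP-CIT supports the diagnosis of
degenerative parkinsonian syndromes. Whether a scan is abnormal often rests
on comparing a quantitative uptake measure against a normative database of
healthy controls. Two obstacles stand in the way of such a database when data
come from many centers: scanners and reconstruction choices bias the
quantitative measure differently, and the measure itself declines with age
and differs by sex. This package implements the full chain that addresses
both: (i) the oversized-VOI ("Southampton") specific binding ratio (SBR)
quantifier, (ii) striatal-phantom cross-calibration that maps every
scanner/reconstruction combination onto a common true-SBR scale, and (iii)
the normative regression layer with prediction intervals that turns a
calibrated SBR into an age/sex-adjusted judgement. Because the underlying
multicenter scans are not redistributable, the package ships a digital
striatal phantom and a synthetic cohort generator with known ground truth;
every stage is exercised end to end against that truth.

## The SBR model and the oversized-VOI estimator

The specific binding ratio compares striatal specific binding with
nondisplaceable background binding,

$$\mathrm{SBR} = C_s / C_r,$$

where $C_s$ is the count concentration in the striatum due to specific
binding only and $C_r$ the count concentration of a reference region. With a
uniform background this equals the striatum:background concentration ratio
minus one, which is what the phantom's filling concentrations (or 1-mL
aliquots in a well counter) provide as ground truth.

Direct striatal sampling is resolution dependent. The oversized-VOI
estimator instead draws a striatal VOI so large that it contains essentially
*all* counts associated with striatal activity, and treats everything in the
VOI beyond background as specific signal:

$$\mathrm{SBR} = \frac{1}{C_{bg}}\cdot
  \frac{C_{\mathrm{StrVOI}} - C_{bg}\, N_{\mathrm{StrVOI}}}{V_{str}},$$

with $C_{bg}$ the mean reference count per voxel, $C_{\mathrm{StrVOI}}$ the
total VOI count, $N_{\mathrm{StrVOI}}$ its voxel count and $V_{str}$ the
striatal volume fixed to 11.2 mL (expressed in voxel units of the grid). Two
properties follow by construction and are verified as tests: adding pure
background voxels to the VOI leaves the estimate unchanged, and the estimate
is exactly invariant to global count rescaling. `vol_str_ml` is interpreted
per hemisphere and is configurable (`quantify_config()`), since published
descriptions leave the per-hemisphere/total convention implicit.

Interhemispheric asymmetry uses the absolute asymmetry index
$\mathrm{AI} = |R - L| / (R + L) \times 200$, on a 0-200 percent-like scale.
It is reported as `NA` when $R + L \le 0$ (possible for cold or
negative-biased measurements; negative SBRs are returned unclamped and
flagged so that calibration can operate on the full linear scale).

## The digital phantom

The digital twin of the anthropomorphic striatal phantom is deliberately
generic, since the oversized-VOI estimator is designed to be insensitive to
exact shape: two mirrored ellipsoids (default semi-axes about 9 x 21 x 14
mm, centred 25 mm lateral of the midline) inside an ellipsoidal background
compartment. Two geometry choices matter and are deliberate:

* **Volume-matched rasterization.** Voxels are ranked by the ellipsoid
  quadratic form and the compartment takes exactly the number of voxels
  whose total volume is nearest 11.2 mL, so the digital hemisphere volume is
  correct to within half a voxel at any spacing in the supported 1-4 mm
  range. Ground-truth SBR would otherwise be confounded by voxelization
  error of a few percent at coarse spacings.
* **Background compartment size.** The background ellipsoid (default
  semi-axes 80 x 95 x 70 mm) is large enough that a striatal VOI with the
  default 20 mm margin stays strictly inside it. Outside the compartment
  voxels hold zero counts, which sit *below* background; if the VOI box
  reached them the estimator's background-cancellation property would break.
  This mirrors the physical constraint that the VOI must stay within the
  uniformly filled head.

The filling sequence reproduces the calibration protocol: 8:1/4:1 nominal
ratios (right/left), then the background raised by 33% with the striata
untouched - giving 6.015:1 and 3.008:1, the exact ratios behind the nominal
"6:1 and 3:1" - and a uniform filling for the zero point.

## The scanner model

Physical projection and reconstruction (attenuation correction, scatter
windows, filtering) are out of scope; phantom cross-calibration only
observes their *net effect* on the measured-vs-true SBR relation, which is
empirically linear. The scanner model therefore applies, in order:

1. a per-condition bias defined directly on the ideal SBR relation,
   $t_{meas} = a\,t + b + c\,t^2$ (gain, offset, optional quadratic term),
   realised by setting striatal compartment excess counts accordingly;
2. an isotropic Gaussian PSF (FWHM in mm; separable, count-conserving);
3. Poisson counting noise scaled so the expected total count equals
   `noise_scale` (default 5e6 in the pipeline configuration, a realistic
   brain-SPECT study total).

The quadratic term (default 0.02 for scatter-corrected conditions in the
demo configuration) emulates the observed phenomenon that scatter-corrected
data retain a residual excess after affine calibration; no physical scatter
model is implied. Defining the bias on the ideal relation (rather than on
raw voxel values) makes the generator's gain the exact ground truth for the
calibration slope, which the tests exploit.

## Quantifier numerics

* **Peak localisation**: the volume is smoothed (Gaussian FWHM 8 mm, to
  stabilise the argmax under Poisson noise), split at the sagittal plane
  through its centre of mass, and the peak of each half taken. A peak must
  exceed 1.05 times the upper quartile of its half's positive smoothed
  values (roughly the background level); otherwise a no-signal /
  degenerate-peak error is raised - a uniformly filled phantom has no
  localisable striatum.
* **Striatal VOI**: a fixed-size axis-aligned box (nominal striatal bounding
  box dilated by a 20 mm margin), clipped to the grid; clipping beyond 5% of
  the nominal volume is recorded in the mask provenance. Intensity never
  influences the mask.
* **Reference region**: brain voxels within a 44-mm axial slab centred on
  the highest striatal activity, minus both striatal VOIs. The brain mask
  thresholds the smoothed volume at 15% of the slab's 99th-percentile
  intensity and is then eroded by 20 mm. The erosion depth is the one
  numerically consequential choice: the background mean multiplies the full
  VOI voxel count in the SBR formula, so a fraction of a percent of
  partial-volume bias at the compartment edge translates into several
  percent of SBR error; eroding by roughly 3 PSF standard deviations
  (20 mm covers any PSF up to ~12 mm FWHM) removes it. Reference counts are
  always taken from the original, unsmoothed volume, so no noise bias is
  introduced.
* **Uniform fillings** are quantified with VOIs located on the hottest
  filling of the same series (`fit_calibration_from_series()` does this
  automatically): the phantom does not move between fillings, and the zero
  point is needed for the calibration line.

With these settings the estimator recovers ratio-minus-one exactly on
unblurred phantoms and to well within 1% under a 12-mm PSF.

## Calibration

One curve per (scanner, reconstruction-condition) pair: ordinary least
squares of measured SBR (Y) on true SBR (X), matching the plotting
convention of phantom calibration experiments, inverted at application time
($\mathrm{cal} = (m - b)/a$). Both hemispheres of every filling contribute a
point. Curves with slope $\le 0.1$ or $r < 0.9$ are rejected - phantom
series are near-perfectly linear, so a poor fit indicates an acquisition
problem, not a usable correction. Left and right SBRs share the curve. The
alternative orientation (regress true on measured) is available by swapping
the arguments of `fit_calibration()` and applying the line directly.

## The synthetic cohort

`generate_cohort()` draws demographics - age uniform on 30-83 years, 54.7%
female (140/256), scan start time normal (3.5 plus or minus 0.5 h, spanning the two
serial-scan start times of about 3.1 and 3.8 h, truncated positive) - and
places the average SBR on the normative plane

$$\mathrm{SBR} = 10.610 - 0.063\,\mathrm{age} + 0.263\,\mathrm{start}
  + 0.461\,[\mathrm{female}] + \varepsilon,\qquad
  \varepsilon \sim N(0, 1.38^2).$$

The residual SD default of 1.38 is chosen so the large-n 95% prediction
half-width is about 2.70 SBR units, the constant gap between decade means
and lower prediction limits in the published decade table. The left/right
split draws a *signed* asymmetry from the AI plane
($2.885 + 0.031\,\mathrm{age} - 0.546\,[\mathrm{female}]$, SD 3.5, a value
consistent with the published upper prediction limits) and folds it to the
absolute AI; its positive mean encodes the reported slight right-side
dominance. With both residual SDs zero every record lies exactly on both
planes, which the interpolation tests use. The published AI regression also
lists a small, nonsignificant start-time term (-0.037/h); the generator
default uses the published prediction formula, which omits it.

`bias_cohort()` then turns true SBRs into condition-measured ones with the
same affine-on-SBR model as the phantom simulator, so harmonization can be
tested on cohorts with known ground truth.

What the generator does *not* emulate: multiple scans per subject with
shared subject-level random effects (records are independent, as the pooled
510-scan analysis also assumes), subfield (caudate/putamen) structure,
handedness, and any non-linear age trend. Passing tests therefore certify
the estimation machinery, not those aspects of real data.

## Normative layer

* Simple and multiple regressions are ordinary least squares (`lm`);
  confidence and prediction intervals use the exact t-based formulas, with
  the unscaled coefficient covariance stored so intervals survive JSON
  serialization. The degenerate zero-residual case collapses both intervals
  onto the fit.
* The decade-by-sex summary defaults to regression-predicted values at
  decade midpoints (34.5, 44.5, ...): the published decade means are exactly
  linear across decades and equal the group regression lines at midpoints,
  so that is the reporting convention reproduced here; raw within-bin means
  are available via `mode = "raw"`.
* The agreement statistic is the two-way random-effects,
  absolute-agreement, single-measure intraclass correlation (ICC(2,1)) -
  the form that penalises exactly the systematic scale/offset disagreement
  calibration is meant to remove - with the standard F-based confidence
  interval; the consistency form ICC(3,1) is available via
  `form = "consistency"`. No installed package provides ICC, so the mean
  squares are computed directly and cross-checked in tests against an
  independent `aov()`-based oracle.
* ANOVA effect tests are Type III with a sum-coded sex factor, age and
  start time continuous, and the sex-by-age interaction, via `car::Anova`.
* `zscore_subject()` reports the standardized residual and flags
  observations below the lower 95% prediction limit - at the 60-69 decade
  this operating point corresponds to roughly a 35% reduction from the
  expected SBR.
* p-values below 1e-15 are formatted as "< 1e-15", never as zero.

## Problem sizes and numerical tolerances

The test suite and the analysis scripts use 2-3 mm voxels (grids of roughly
60-100 voxels per axis), phantom series of 2-3 fillings on 1-2 emulated
scanners, cohorts of 510 records for the workflow demonstration and 5,000
for parameter recovery, 10,000 fresh draws for prediction-interval coverage,
and 200-400 replicates for the agreement-improvement and type-I-error
simulations. Noise-free identities are asserted at 1e-9 to 1e-12; stochastic
recoveries at 3 standard errors; coverage at plus or minus 1.5 percentage
points.

## Known limitations

* The digital phantom is a generic twin: the physical product's crescent
  striatal geometry and exact head dimensions are not public. The
  estimator's shape insensitivity is the mitigation, and is itself tested.
* Reconstruction physics is emulated only as the (gain, offset, quadratic)
  bias on the SBR relation; conclusions about any *specific* physical
  correction are out of scope.
* Calibration curves are per (scanner, condition) pair; collimator-level
  pooling is the caller's choice of key.
* The normative layer treats repeated scans as independent records; a
  subject-ID column is carried so users can average per subject first.
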