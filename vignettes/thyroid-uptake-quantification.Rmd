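---
title: "Quantifying pertechnetate thyroid uptake: TcTU, UR and the area-corrected CUR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pertechnetate thyroid uptake: TcTU, UR and the area-corrected CUR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyroscint)
```

## The measurement problem

Technetium-99m pertechnetate planar scintigraphy yields two families of
thyroid-uptake measures. The quantitative **TcTU** — the percentage of the
injected activity trapped in the gland at imaging time — is the accurate
reference, but it needs syringe dose-calibrator assays before and after
injection, a camera calibration factor, decay correction and (when the
injection extravasates) a leakage acquisition. The semiquantitative
**uptake ratio UR** needs only the image: it is the ratio of count
*concentrations* (counts per cm²) between a thyroid ROI and a background
ROI drawn under the gland,

$$\mathrm{UR} = \frac{C_T / S_T}{C_B / S_B}.$$

Because UR is a concentration ratio, it is blind to gland size. A small
postoperative remnant concentrating tracer into a few cm² shows a high
local concentration — and hence a "normal" or even "high" UR — while its
total uptake (TcTU) is clearly decreased. Conversely a large goitre
dilutes its uptake over a large area and UR under-reads it. The
**corrected uptake ratio CUR** repairs exactly this by rescaling UR with
the subject's functional gland area relative to a standardized
(control-mean) thyroid area $S_{T1}$:

$$\mathrm{CUR} = \mathrm{UR}\cdot\frac{S_T}{S_{T1}}
             = \frac{C_T / S_{T1}}{C_B / S_B}.$$

Equivalently, CUR is the ratio of the *counts per standardized thyroid
size* $C_{T1} = C_T/S_{T1}$ to the background concentration
$C_{B1} = C_B/S_B$; these standardized intermediates are reported by
`quantify_study()`. The identity $\mathrm{CUR}/\mathrm{UR} = S_T/S_{T1}$
holds for every subject and is asserted in the test suite.

TcTU follows the standard net-counts-over-injected-counts algorithm:

$$\mathrm{TcTU}(\%) = 100\cdot
  \frac{C_T - (C_B/S_B)\,S_T}{A_{\mathrm{net}}(t_{\mathrm{img}})\cdot f \cdot D},$$

where $A_{\mathrm{net}}$ is the pre-minus-post syringe activity decayed
to the imaging start time (minus any leakage activity, itself estimated
as leakage count rate divided by the calibration factor and
decay-corrected), $f$ the calibration factor in counts s⁻¹ MBq⁻¹ and
$D$ the acquisition duration. Decay uses
$A(t) = A_0\,2^{-\Delta t/T_{1/2}}$ with $T_{1/2} = 6.0067$ h. The
reference time for decay correction is the thyroid acquisition start; a
negative background-subtracted numerator is clipped to zero and flagged
rather than reported as a negative percentage.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `s_t1` | 22.06 cm² | standardized thyroid area; the control-group mean. The pipeline refits it as the synthetic control mean unless fixed. |
| `half_life_h` | 6.0067 h | Tc-99m physical half-life |
| reference-range rounding | 2 dp (uptake), 1 dp (area) | limits are rounded before classification so reported and operative limits agree; an unrounded mode is available since it is equally defensible |
| chi-square method | likelihood-ratio G | Pearson and Yates-corrected Pearson available by flag |
| WLS weights | two-pass variance function | unit weights and user weights supported |

Reference ranges are parametric 95% intervals, mean ± 1.96 SD, fit on
the control group; boundary values classify as *normal* (closed
interval). Gland areas are stratified *small/normal/large* against the
control-area range the same way.

### Why the likelihood-ratio chi-square is the default

Rates are compared on 2×2 (or r×2) concordant/discordant tables. Both
the Pearson statistic $\sum (O-E)^2/E$ and the likelihood-ratio
statistic $G = 2\sum O\ln(O/E)$ are implemented and cross-checked
against each other (they agree asymptotically; a property test asserts
agreement within 5% on large balanced tables) and against
`chisq.test()`. G is the default because it is the flavor consistent
with the published concordance analyses this package's checks
reproduce; either can be selected per call.

### WLS weighting

The regression layer fits TcTU on $S_T$, UR or CUR by weighted least
squares, reporting raw slopes, standard errors, standardized
coefficients $\beta = b\,\mathrm{sd}_w(x)/\mathrm{sd}_w(y)$, $R$,
adjusted $R^2$ and the model $F$. Uptake data are heteroscedastic — the
spread grows with the mean, as is typical for count-derived quantities —
so the default weights come from a two-pass variance-function fit:
regress the log squared OLS residuals on the log absolute fitted
values and weight by the inverse fitted variance. No published weighting
scheme exists to validate against, so unit weights (exact OLS, asserted
to machine precision in the tests) and user-supplied weights are equally
first-class, and regression coefficients are never treated as
reproduction targets.

## The synthetic phantom: what it emulates and what it does not

`generate_phantom()` builds a two-lobed elliptical gland (aspect ratio
1.8, 0.6 cm inter-lobe gap, optional isthmus band) over a background
strip placed below the gland, on a 256×256 matrix by default. Expected
pixel means are the sum of a uniform background concentration and, on
gland pixels, the gland's share of the injected counts spread uniformly
over the *rasterized* mask area; observed counts are independent Poisson
draws. Because areas are always computed from the rasterized mask, the
mask area and the $S_T$ entering UR/CUR agree exactly, and quantifying a
noiseless phantom returns `true_tctu` to machine precision — an oracle
equivalence the suite asserts for several uptake levels.

Default acquisition conditions are one fixed protocol: 148 MBq injected
(mid-range of a typical 74–185 MBq administration), camera sensitivity
90 counts s⁻¹ MBq⁻¹ (a typical planar LEHR figure), imaging for 300 s
starting 20 min post injection. The background concentration default
(1170 counts cm⁻²) was chosen once so that a control-mean phantom
(TcTU 2.17%, area 22.06 cm²) lands at UR ≈ 4.2, the control-group
level; it was not tuned further.

Cohort emulation (`sample_cohort_truth()`, `generate_cohort()`) draws
per-subject true uptake from group-wise log-normal distributions
(resampled above 100%) and functional areas from truncated normals.
The default design (`default_cohort_design()`) mirrors a mixed thyroid
clinic: a control group (TcTU median 2.17%, area 22.06 ± 2.82 cm²) plus
hyperthyroid, goitre, destructive-thyroiditis, hypothyroid,
postoperative-remnant, nodule and autoimmune groups. Only the control
uptake and the control area summary are anchored to published values;
disease-group uptake medians were derived once from the corresponding
published CUR medians through the control-group linear relation between
CUR and TcTU, and the area means were chosen so that the small/normal/
large strata are all well populated. These are modeling choices —
no per-group joint distribution of uptake and area exists to validate
against.

The phantom deliberately omits scatter, attenuation, collimator blur,
septal penetration, patient motion and intra-gland heterogeneity
(nodules). Passing tests therefore demonstrate that the *estimators*
invert the forward model correctly and behave sensibly under pure
counting statistics — not that they are robust to the physics a real
camera adds. In particular, absolute TcTU accuracy on real data depends
on the camera calibration factor absorbing attenuation and geometry,
which is outside this package's scope.

## Numerical and design choices

* **Rasterization rule.** Pixel-centre inclusion under the even-odd
  rule with a half-open boundary (left/top edges in, right/bottom out),
  so polygon ROIs rasterize identically across platforms and adjacent
  polygons tile without double counting. A fine circular polygon's
  rasterized area converges to $\pi r^2$ within 2% (tested).
* **Pixel spacing is never inferred** from acquisition zoom; it must
  come from image metadata or configuration.
* **Seeding.** One cohort seed; per-image seeds derive from it by
  counter, so cohorts are bit-reproducible and single phantoms can be
  regenerated in isolation. Phantom generation saves and restores the
  caller's RNG state.
* **Degenerate inputs.** Empty ROIs, zero background counts,
  non-positive areas, negative net injected activity, rank-deficient
  designs and zero-marginal contingency tables all raise immediately;
  the pipeline downgrades only the stratum-level rate test to an NA
  statistic when a stratum is empty or both rates are 0/100%.
* **S_T1.** The standardized area defaults to the control-group mean
  measured area of the cohort being analyzed (that is how the reference
  standard is defined); it can be pinned to any value, e.g. 22.06 cm²,
  for comparability across cohorts.

## Problem sizes used by the automated checks

The test suite and the acceptance script run the cohort pipeline at
389 subjects (the published cohort size) on 128×128 or 256×256
matrices, 200 Poisson replicates for TcTU parameter recovery, and 1000
null replicates for the Mann-Whitney type-I-error check. These sizes
give Monte-Carlo errors comfortably inside the asserted tolerances
(e.g. the recovery check asserts a 3-standard-error band around the
true uptake).

## Known limitations

* The phantom's idealized physics (above): results quantify estimator
  correctness, not clinical accuracy.
* Reference ranges are parametric mean ± 1.96 SD by design;
  percentile-based intervals are out of scope.
* Published patient-level regression coefficients and group Z
  statistics cannot be reproduced without the raw data; the package
  substitutes property-based checks (identity relations, parameter
  recovery, OLS equivalence, type-I error calibration).
* DICOM reading is not included; images enter through the documented
  plain-text grid format, and DICOM pixel data must be converted with
  explicit pixel-spacing metadata.
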