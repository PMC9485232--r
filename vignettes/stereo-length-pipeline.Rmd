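---
title: "Methods: parallax-based fish sizing with finscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallax-based fish sizing with finscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finscale)
```

## The measurement model

A vertical-baseline stereo rig images the same scene from two lenses
`B = 0.08` m apart. Under an aligned pinhole model a world point
`(x, y, z)` projects to

```
u = f_x · x/z + s · y/z + c_x
v = f_y · y/z + c_y
```

with the y-coordinate shifted by `B` for the lower camera, so the point's
disparity (here called *translation*, measured as the Euclidean pixel
distance between its two images) is `d = f·B/z`. The metric footprint of
one pixel at depth `z` is `z·10⁶/f` micron, which equals `B·10⁶/d` —
independent of the focal length. That hyperbola is the analytic oracle for
the whole pipeline: everything else is machinery for estimating `d`
robustly and converting pixel measurements through it.

The production path does not use the hyperbola directly. Instead, the
scale-vs-translation relationship is *calibrated empirically* from
chessboard poses, because the real rig deviates from the ideal model
(refraction through the housing and water, lens distortion, small
misalignments). The calibration absorbs those effects without modelling
them: this mirrors how the field system handles refraction, and is why the
rig type's `medium_index` is only a synthetic-data knob (a multiplicative
focal scaling, 1.0 in air), not a ray-traced flat-port model.

Assumptions worth stating: the two cameras are synchronized and share
resolution; the baseline is purely vertical; fish landmarks (snout tip,
base of the middle caudal rays) are visible in both frames; and each fish
is approximately fronto-parallel — a yawed fish of true length `L` presents
a visible segment of `L·cos θ`, and no pose correction is applied, so yaw
always biases estimates downward and inflates the dispersion of estimated
length distributions. This matches the heavier tails seen when comparing
image-estimated to hand-sampled distributions.

## Calibration model and its numerical limits

Each chessboard pose yields landmark pairs whose physical separation is a
known integer number of 27-mm squares. One observation per pair:
`scale = separation(micron) / pixel distance` in the reference (upper)
frame, and `translation` = the mean of the two endpoints' disparities.
`fit_scale_model()` fits scale as a polynomial in translation by penalized
least squares on standardized features: degree 3 and `lambda = 0` give the
plain cubic; `lambda > 0` gives the polynomial ridge variant (one code
path covers both published descriptions of the fit). The intercept is
never penalized, so as `lambda → ∞` predictions shrink monotonically to
the mean scale.

A numerical fact that shapes the test design: **a cubic cannot track the
parallax hyperbola within 1 % over the full working range**. Over
translations 140–600 px the best least-squares cubic has relative errors
of roughly 2 % mid-range and up to ~7 % at the far edge — an
approximation-theory limit, not a fitting defect. The cubic is kept as the
default because it is the production model and, on realistic calibration
data (208 jittered observations), explains essentially all variance
(R² ≈ 0.99 here; ≈ 0.9 on real data). Where an oracle-exact model is
needed — the noiseless recovery properties in the test suite — we fit
degree 5 with `weights = "relative"` (rows weighted `1/scale²`, so the fit
minimizes *relative* error, the scale on which measurement accuracy is
judged); that combination tracks the hyperbola within 0.93 % across
140–600 px. Increasing degree from 3 to 5 never worsens the training-range
error, which the suite also asserts.

Other numerical choices:

* **Validity range.** Lower bound fixed at the 140-px quality threshold;
  upper bound at the largest training translation. Out-of-range queries
  warn and extrapolate rather than error, because field disparities can
  slightly exceed the calibrated range; `scale_in_range()` exposes the
  flag. Positivity of the fitted curve is checked on a 256-point grid at
  fit time.
* **Degenerate inputs.** A constant response makes R² undefined; it is
  reported as `NA` with an explicit flag rather than 0, to avoid a
  silently misleading diagnostic. All-identical translations raise a rank
  error; fewer than `degree + 2` observations raise a fit error.
* **Serialization.** Models are stored as JSON with both the raw-basis
  coefficients (lowest order first) and the standardization constants, so
  predictions round-trip losslessly; a rig hash ties a model to the rig it
  was calibrated for, and `measure` refuses a mismatched rig.
* **Distortion.** Two-coefficient Brown radial model on normalized
  coordinates (the rig reports only radial distortion; no tangential
  terms). Undistortion inverts the model by fixed-point iteration
  (tolerance 1e-12 normalized, cap 100 iterations, convergence verified
  against the forward model with an explicit residual check); the round
  trip is exact to well below 1e-6 px for |k1| ≤ 0.3 within the unit
  radius.
* **Confidence band.** The calibration plot's 95 % band is a pointwise
  approximation from the residual standard deviation (mean ± 1.96·σ); the
  exact construction used in the original figure is unspecified, so the
  band is documented as approximate.

## Measurement and quality control

`estimate_lengths()` measures the snout–caudal pixel distance in the
reference frame a (the same frame that anchors calibration; averaging both
frames is an option), takes the per-fish translation as the mean of the
two landmarks' disparities (the same averaging used for chessboard pairs),
and applies the threshold *inclusively*: records are discarded only when
translation falls strictly below 140 px. The filter is idempotent and
partitions any batch exactly. Validation against targets of known length
reports two statistics together: the mean absolute error in cm and the
mean absolute percentage error — the published accuracy figure quotes
"MAPE" in both cm and % form, so both are first-class outputs.

The disparity of a landmark is the Euclidean norm of its pixel offset
(`"vertical"` is available as an option): the published description —
a distance in pixels between the same point in the two images — does not
choose a component, and for this rig the vertical term dominates anyway.

## Distribution comparison

`compare_distributions()` records an auditable decision trail: Shapiro–
Wilk per group, then Levene across groups — median-centred
(Brown–Forsythe) by default, as the more robust variant; mean-centred is
an option since the original choice is unstated — then a Welch F test when
Levene rejects at `alpha = 0.05`, else the pooled-variance F test. Q-q
pairs evaluate both groups' type-7 quantiles at the plotting positions of
the smaller group. Histograms use half-open integer-edged 1-cm bins
`[k, k+1)` labeled by the left edge. The mean-difference percentage uses
the image-estimated mean as denominator: with the reference field means
this reproduces both printed figures (3.0 % for length and 3.6 % for
weight — the weight pair `(606 − 585)/585 = 3.59 %` fixes the convention,
since `/606` would print 3.5 %).

## What the synthetic generators emulate — and what they do not

The generators reproduce the *geometry and noise structure* of the field
protocol with exact ground truth:

* `generate_chessboard_session()` — 52 poses × 4 landmark pairs (208
  observations) by default, pose distances drawn so disparities cover
  150–600 px uniformly, pairs spanning 2–6 squares at random positions
  and orientations on the board, Gaussian corner jitter.
* `generate_silhouette_validation()` — 17 stereo images, each containing
  all four reference silhouettes (22.0, 24.2, 29.0, 33.6 cm),
  fronto-parallel at distances whose disparities decrease evenly from 600
  to 150 px, so every measurement stays above threshold (68 measurements
  total).
* `generate_fish_population()` — SL ~ Normal(27.1, 1.6) cm truncated at
  5 cm, n = 190; weights from `W = 0.1342·SL^2.5465` with mean-one
  log-normal noise, CV 0.08 by default. The CV was chosen once so that
  length spread (contributing b·CV_L ≈ 15 % weight CV) plus residual noise
  reproduces the observed ≈ 103 g SD around 606 g; it also lands the
  log-scale allometric R² near the published 0.755. (The field sample size
  is quoted variously as 190, 198 and 200 in the source material; the
  generator uses 190, matching the reported comparison group.)
* `generate_fish_scene()` — distances uniform over the configured range,
  yaw Normal(0, `yaw_sd`), landmarks are the projected endpoints of the
  foreshortened segment plus jitter; truth flags which fish should fail
  the 140-px filter. The default range [0.3, 2.0] m straddles the
  threshold distance (≈ 1.84 m on the default rig); emulating the field
  discard rate of roughly half requires extending the range (e.g. to
  ≈ 3.5 m), which the examples do explicitly rather than changing the
  default.

The 2-px landmark jitter is a modeling choice: no pixel-scale detector
error is published for the landmark CNN (its reported error is on
normalized coordinates), so 2 px stands in for detector noise and is the
pinned default for the validation experiments.

Fish are line segments (two landmarks), not rendered bodies: the detection
and landmark networks are out of scope, so pixels beyond the landmarks
carry no information. Consequently, passing synthetic validation
demonstrates the *geometric and statistical* correctness of the pipeline —
calibration, parallax scaling, QC, allometry, comparison statistics — but
says nothing about detector performance on real imagery: occlusion,
turbidity, lighting, fish curvature (only rigid yaw is modelled), schooling
density, or landmark mislocalization beyond isotropic Gaussian jitter.

## Default rig parameters

| Parameter | Default | Why |
|---|---|---|
| resolution | 3280 × 2464 px | sensor of the reference rig |
| focal (px) | 3218.68 both axes | from the 54° horizontal FOV; square pixels |
| baseline | 0.08 m, vertical | reference rig geometry |
| threshold | 140 px, inclusive | published QC bound; "below" discards |
| jitter SD | 2 px | stand-in for landmark-detector noise |
| degree / λ | 3 / 0 | production cubic; λ exposes the ridge variant |

The square-pixel choice deserves a note: derived per-axis, the nominal
FOVs give `f_x = 3218.7` and `f_y = 3295.1` (a 2.4 % anisotropy that would
make the micron/pixel scale direction-dependent and bias horizontal fish
against a vertical-disparity calibration). The sensor has square pixels,
and the square-pixel focal implies a vertical FOV of 41.9°, consistent
with the nominal 41° to within rounding — so the default rig uses one
focal for both axes, and the hand-checked projection values
(`u − c_x = 321.87` px for a 0.1 m offset at 1 m; disparity 257.49 px at
1 m) follow from it.

## Problem sizes

The test suite and the acceptance script run the experiments at their
reference sizes — 208 calibration observations, 68 silhouette
measurements, populations of 120–190 fish — plus property checks over a
few dozen randomized draws each; the full suite completes in well under a
minute on a single core.

## Known limitations

No pose correction (yaw bias is documented, not removed); no epipolar
rectification or bundle adjustment (the rig is assumed aligned; real
misalignment is absorbed by the empirical calibration only to the extent
it is distance-stable); radial-only distortion; the back-transform bias of
the log-log allometric fit is not corrected by default (the reference
coefficients carry none; `bias_correction = TRUE` enables the log-normal
factor); and the cubic calibration extrapolates poorly outside its
training range — extrapolated predictions are flagged, and users should
treat them accordingly.
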