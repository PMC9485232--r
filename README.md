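# finscale

Stereo-parallax morphometry for farmed fish: estimate standard length (SL)
and weight of free-swimming fish from landmark annotations on synchronized
stereo image pairs.

## The problem

Routine length and biomass estimation in sea cages is usually done by
netting and hand-measuring a subsample — invasive, slow, and biased toward
catchable fish. A fixed stereo camera (two lenses a known baseline apart,
8 cm vertical in the reference rig) offers a non-invasive alternative: the
same physical point translates between the two simultaneous frames by a
pixel *disparity* `d` that is inversely proportional to its distance `z`
from the rig,

```
d = f · B / z        (f: focal length in pixels, B: baseline in metres)
```

so the metric size of one pixel at the fish's distance — the
micron-per-pixel *scale* — follows from the parallax alone:

```
scale = B · 10⁶ / d   [micron/pixel]
```

In practice the mapping from translation to scale is calibrated
empirically: a chessboard of known square size (27 mm) is posed at many
distances, each pose yielding landmark pairs with known physical
separation, and a degree-3 polynomial (optionally ridge-penalized) is
fitted to scale-versus-translation. A fish's SL is then

```
SL [cm] = pixel_length · scale(translation) / 10⁴
```

where `pixel_length` is the snout-to-caudal-base pixel distance in the
reference frame and `translation` is the mean disparity of the two
landmarks. Fish whose translation falls below 140 px (too distant for a
reliable parallax) are discarded by quality control. Weights follow the
allometric length-weight relationship `W = a·SLᵇ`, fitted by ordinary
least squares of `log W` on `log SL`. Estimated and field-sampled size
distributions are compared with Shapiro–Wilk, Levene and Welch tests,
matched q-q quantile pairs, and 1-cm histograms.

The package implements the full pipeline plus seed-deterministic synthetic
generators (chessboard sessions, silhouette validation sets, fish
populations and free-swimming scenes) that stand in for the cameras and
the CNN landmark detectors, with exact ground truth for every downstream
statistic.

## Worked example

```r
library(finscale)

# 1. Calibrate: 52 chessboard poses x 4 landmark pairs, 2-px jitter
cfg     <- scene_config(seed = 7)
session <- generate_chessboard_session(52, 4, cfg, seed = 7)
model   <- fit_scale_model(chessboard_observations(session$annotations))
model
#> Translation -> scale calibration (degree 3, lambda = 0)
#>   n = 208 observations, valid range [140.0, 598.6] px
#>   R^2 = 0.9981, residual sigma = 4.50 micron/px

# 2. Validate on silhouettes of known size (17 images x 4 targets)
val <- generate_silhouette_validation(cfg = cfg, seed = 8)
est <- estimate_lengths(val$annotations, model)
joined <- dplyr::inner_join(val$truth, est, by = "fish_id")
length_validation(joined$true_length_cm, joined$standard_length)
#> Length validation over 68 measurements
#>   mean absolute error: 0.40 cm
#>   mean absolute percentage error: 1.47 %

# 3. Length-weight relationship on a sampled population
pop <- generate_fish_population(population_config(seed = 9))
lwr <- fit_lwr(pop)
lwr
#> Length-weight relationship: W = 0.1500 * SL^2.5130
#>   n = 190, R^2 (log scale) = 0.772
predict_weight(lwr, 27.1)
#> [1] 598.6218
```

The calibration R² says the cubic captures essentially all of the
scale-translation relationship on jittered synthetic data; the 0.40 cm /
1.5 % silhouette errors quantify the measurement accuracy achievable with
2-px landmark noise; and the fitted allometry converts lengths to weights
(~599 g for a 27.1 cm seabream).

Each fitted object supports `tidy()`, `glance()` and `autoplot()`;
`compare_distributions()` produces the test cascade and q-q machinery for
sampled-versus-estimated comparisons. A command-line wrapper
(`exec/finscale`) exposes `calibrate`, `measure`, `validate`, `weigh`,
`compare` and `simulate` subcommands over the same functions.

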