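# Shared fixtures: tiny in-code annotation tables and reference models.

# A noiseless calibration model that tracks the parallax hyperbola
# scale = B * 1e6 / d within 1% across [140, 600] px. A cubic cannot do
# this over such a wide disparity range (its best relative error is several
# percent), so oracle-recovery checks use degree 5 with relative weighting.
hyperbola_model <- function(baseline = 0.08, degree = 5,
                            range_px = c(140, 600), n = 200) {
  d <- seq(range_px[1], range_px[2], length.out = n)
  obs <- tibble::tibble(translation = d,
                        scale = baseline * 1e6 / d)
  fit_scale_model(obs, degree = degree, weights = "relative",
                  min_translation = range_px[1])
}

# Calibration annotations for a single landmark pair, built from explicit
# pixel coordinates: endpoints e1/e2 in frames a/b.
pair_annotation <- function(e1_a, e2_a, e1_b, e2_b, squares = 5,
                            pose = "pose1", pair = "p1") {
  tibble::tibble(
    session_id = "s1",
    pose_id = pose,
    pair_id = pair,
    endpoint = rep(1:2, 2),
    frame = rep(c("a", "b"), each = 2),
    u = c(e1_a[1], e2_a[1], e1_b[1], e2_b[1]),
    v = c(e1_a[2], e2_a[2], e1_b[2], e2_b[2]),
    squares_spanned = squares
  )
}

# Fish annotations for one fish from explicit snout/caudal points per frame.
fish_annotation <- function(fish_id, snout_a, caudal_a, snout_b, caudal_b) {
  tibble::tibble(
    fish_id = fish_id,
    frame = rep(c("a", "b"), each = 2),
    landmark = rep(c("snout", "caudal"), 2),
    u = c(snout_a[1], caudal_a[1], snout_b[1], caudal_b[1]),
    v = c(snout_a[2], caudal_a[2], snout_b[2], caudal_b[2]),
    confidence = 1
  )
}
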