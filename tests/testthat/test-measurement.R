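test_that("fish translation is the mean of the two landmark disparities", {
  # both landmarks translate exactly 200 px
  ann <- fish_annotation("f1", c(100, 100), c(640, 100),
                         c(100, 300), c(640, 300))
  expect_equal(fish_translation(landmark_pairs(ann)), 200)

  # snout 180 px, caudal 220 px -> 200
  ann <- fish_annotation("f2", c(100, 100), c(640, 100),
                         c(100, 280), c(640, 320))
  expect_equal(fish_translation(landmark_pairs(ann)), 200)
})

test_that("threshold filter is inclusive, idempotent and partitions a batch", {
  expect_false(passes_threshold(139.9))
  expect_true(passes_threshold(140.0))
  set.seed(9)
  tr <- runif(500, 100, 200)
  keep <- passes_threshold(tr)
  k <- sum(tr < 140)
  expect_equal(sum(keep), 500 - k)
  # idempotent: every surviving record survives a second filtering
  expect_true(all(passes_threshold(tr[keep])))
  # exact partition
  expect_equal(sum(keep) + sum(!keep), 500L)
})

test_that("length estimation combines pixel length, scale and threshold QC", {
  model <- hyperbola_model()

  # pixel length 540 px at a translation where the scale is 500 micron/px
  ann <- fish_annotation("f1", c(100, 500), c(640, 500),
                         c(100, 660), c(640, 660))  # translation 160 px
  est <- estimate_lengths(ann, model)
  expect_true(est$qc_pass)
  expect_equal(est$pixel_length, 540)
  expect_equal(est$translation, 160)
  expect_equal(est$standard_length, 540 * 500 / 1e4, tolerance = 0.01)

  # below-threshold fish carries no length
  low <- fish_annotation("f2", c(100, 500), c(640, 500),
                         c(100, 620), c(640, 620))  # translation 120 px
  est <- estimate_lengths(low, model)
  expect_false(est$qc_pass)
  expect_match(est$qc_reason, "below 140")
  expect_true(is.na(est$standard_length))

  # degenerate landmarks fail QC with a reason
  degen <- fish_annotation("f3", c(100, 500), c(100, 500),
                           c(100, 660), c(100, 660))
  est <- estimate_lengths(degen, model)
  expect_false(est$qc_pass)
  expect_match(est$qc_reason, "degenerate")

  expect_error(estimate_lengths(ann, list(a = 1)), "scale_model")
})

test_that("noiseless synthetic fish are recovered within 1% at any depth", {
  model <- hyperbola_model()
  rig <- default_rig()
  f <- rig$camera_a$focal_px[2]
  set.seed(21)
  for (i in 1:20) {
    z <- runif(1, 0.45, 1.8)          # keeps f*B/z >= 143 px
    sl <- runif(1, 15, 40)
    x0 <- runif(1, -0.1, 0.1) * z
    y0 <- runif(1, -0.08, 0.08) * z
    pts <- tibble::tibble(x = x0 + c(-0.5, 0.5) * sl / 100, y = y0, z = z)
    pa <- project_points(pts, rig, "a")
    pb <- project_points(pts, rig, "b")
    ann <- fish_annotation("f", c(pa$u[1], pa$v[1]), c(pa$u[2], pa$v[2]),
                           c(pb$u[1], pb$v[1]), c(pb$u[2], pb$v[2]))
    est <- estimate_lengths(ann, model)
    expect_true(est$qc_pass)
    expect_equal(est$standard_length, sl, tolerance = 0.01)
  }
})

test_that("estimated length is independent of lateral position in frame", {
  model <- hyperbola_model()
  rig <- default_rig()
  z <- 1.1; sl <- 27.1
  ests <- vapply(c(-0.15, 0, 0.2), function(x0) {
    pts <- tibble::tibble(x = x0 + c(-0.5, 0.5) * sl / 100, y = 0.05, z = z)
    pa <- project_points(pts, rig, "a")
    pb <- project_points(pts, rig, "b")
    ann <- fish_annotation("f", c(pa$u[1], pa$v[1]), c(pa$u[2], pa$v[2]),
                           c(pb$u[1], pb$v[1]), c(pb$u[2], pb$v[2]))
    estimate_lengths(ann, model)$standard_length
  }, numeric(1))
  expect_lt(diff(range(ests)), 1e-9)
})

test_that("yaw foreshortening biases estimates by cos(theta), never upward", {
  model <- hyperbola_model()
  cfg0 <- scene_config(landmark_jitter_sd = 0, distance_range = c(0.6, 1.2))
  pop <- tibble::tibble(fish_id = "f1", standard_length_cm = 30)
  for (theta in c(10, 25, 40)) {
    cfg <- scene_config(landmark_jitter_sd = 0, yaw_sd = 0,
                        distance_range = c(0.9, 0.9))
    scene <- generate_fish_scene(pop, cfg, seed = 5)
    # impose the yaw analytically: visible length is SL * cos(theta)
    pop_yawed <- dplyr::mutate(pop,
      standard_length_cm = standard_length_cm * cos(theta * pi / 180))
    yawed <- generate_fish_scene(pop_yawed, cfg, seed = 5)
    est <- estimate_lengths(yawed$annotations, model)
    expect_equal(est$standard_length, 30 * cos(theta * pi / 180),
                 tolerance = 0.01)
    expect_lt(est$standard_length, 30)
  }
})

test_that("validation report computes MAE and MAPE", {
  # perfect estimates
  rep0 <- length_validation(c(10, 20), c(10, 20))
  expect_equal(rep0$mae_cm, 0)
  expect_equal(rep0$mape_pct, 0)

  # the four silhouette lengths with hand-computed errors
  rep1 <- length_validation(c(22.0, 24.2, 29.0, 33.6),
                            c(22.5, 23.8, 29.9, 32.4))
  expect_equal(rep1$mae_cm, 0.75)
  expect_equal(rep1$mape_pct, 2.65, tolerance = 1e-3)

  # single pair
  rep2 <- length_validation(10, 11)
  expect_equal(rep2$mae_cm, 1)
  expect_equal(rep2$mape_pct, 10)

  expect_error(length_validation(c(1, 2), 1), "equal length")
  expect_equal(nrow(tidy(rep1)), 4)
  expect_equal(glance(rep1)$mape_pct, rep1$mape_pct)
})
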