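test_that("chessboard observations derive scale and translation per pair", {
  # pair spanning 5 squares (135 mm) imaged 270 px apart in frame a,
  # endpoints translated 250 and 260 px vertically between frames
  ann <- pair_annotation(
    e1_a = c(100, 100), e2_a = c(370, 100),
    e1_b = c(100, 350), e2_b = c(370, 360),
    squares = 5
  )
  obs <- chessboard_observations(ann)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$scale, 500)        # 135000 micron / 270 px
  expect_equal(obs$translation, 255)  # mean of 250 and 260

  # zero pixel separation is rejected
  degen <- pair_annotation(c(10, 10), c(10, 10), c(10, 200), c(10, 200))
  expect_warning(out <- chessboard_observations(degen), "degenerate")
  expect_equal(nrow(out), 0L)

  # incomplete correspondence is skipped with a warning
  partial <- dplyr::bind_rows(ann, pair_annotation(
    c(0, 0), c(100, 0), c(0, 200), c(100, 200), pair = "p2"
  )[-1, ])
  expect_warning(out <- chessboard_observations(partial), "missing")
  expect_equal(out$pair_id, "p1")
})

test_that("a full synthetic session yields 52 x 4 = 208 observations", {
  sess <- generate_chessboard_session(52, 4, scene_config(), seed = 3)
  obs <- chessboard_observations(sess$annotations)
  expect_equal(nrow(obs), 208L)
})

test_that("noiseless fits track the parallax hyperbola", {
  model <- hyperbola_model()
  d <- seq(140, 600, length.out = 301)
  rel_err <- abs(predict_scale(model, d) - 80000 / d) / (80000 / d)
  expect_lt(max(rel_err), 0.01)

  # query at d = 200 recovers ~400 micron/px
  expect_equal(predict_scale(model, 200), 400, tolerance = 0.01 * 400)

  # interpolation at exact training translations
  obs <- tibble::tibble(translation = seq(150, 580, by = 10))
  obs$scale <- 80000 / obs$translation
  m <- fit_scale_model(obs, degree = 5, weights = "relative")
  expect_equal(predict_scale(m, obs$translation), obs$scale,
               tolerance = 0.01)

  # increasing degree from 3 to 5 does not worsen the max relative error
  errs <- vapply(3:5, function(deg) {
    m <- fit_scale_model(obs, degree = deg)
    max(abs(predict_scale(m, obs$translation) - obs$scale) / obs$scale)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("fitted scale model is monotone decreasing over its valid range", {
  sess <- generate_chessboard_session(52, 4, scene_config(), seed = 12)
  obs <- chessboard_observations(sess$annotations)
  model <- fit_scale_model(obs)
  grid <- predict_scale(model, seq(model$valid_range[1], model$valid_range[2],
                                   length.out = 400), warn = FALSE)
  expect_true(all(diff(grid) < 0))
})

test_that("ridge penalty shrinks predictions monotonically toward the mean", {
  set.seed(42)
  d <- runif(60, 150, 600)
  obs <- tibble::tibble(translation = d, scale = 80000 / d + rnorm(60, 0, 5))
  mean_scale <- mean(obs$scale)
  lambdas <- c(0, 1, 10, 100, 1e4, 1e8)
  for (q in c(180, 300, 550)) {
    preds <- vapply(lambdas, function(l) {
      predict_scale(fit_scale_model(obs, lambda = l), q, warn = FALSE)
    }, numeric(1))
    gaps <- abs(preds - mean_scale)
    expect_true(all(diff(gaps) <= 1e-6))
    expect_equal(preds[length(preds)], mean_scale, tolerance = 1e-3)
  }
  # lambda = 0 reproduces the ordinary least-squares cubic
  m0 <- fit_scale_model(obs, lambda = 0)
  lmfit <- lm(scale ~ poly(translation, 3, raw = TRUE), data = obs)
  expect_equal(unname(predict_scale(m0, c(200, 400))),
               unname(predict(lmfit, tibble::tibble(translation = c(200, 400)))),
               tolerance = 1e-6)
})

test_that("degenerate and under-determined fits fail loudly", {
  flat <- tibble::tibble(translation = c(200, 200, 200, 200, 200, 200),
                         scale = c(400, 401, 399, 400, 400, 400))
  expect_error(fit_scale_model(flat), "identical")
  few <- tibble::tibble(translation = c(150, 300), scale = c(533, 267))
  expect_error(fit_scale_model(few), "at least")

  # constant response: fit succeeds, R^2 flagged undefined
  const <- tibble::tibble(translation = seq(150, 500, length.out = 10),
                          scale = 400)
  m <- fit_scale_model(const)
  expect_false(m$r_squared_defined)
  expect_true(is.na(m$r_squared))
  expect_equal(predict_scale(m, 325, warn = FALSE), 400, tolerance = 1e-6)
})

test_that("r_squared matches the hand-computed definition", {
  expect_equal(r_squared(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  y <- c(3, 1, 4, 2)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.8)
  expect_warning(out <- r_squared(c(2, 2, 2), c(1, 2, 3)), "undefined")
  expect_true(is.na(out))
})

test_that("out-of-range queries warn and are flagged as extrapolation", {
  model <- hyperbola_model(range_px = c(150, 600))
  expect_warning(predict_scale(model, 120), "outside")
  expect_false(scale_in_range(model, 120))
  expect_true(scale_in_range(model, 300))
  expect_silent(predict_scale(model, 300))
})

test_that("scale model JSON round-trips losslessly", {
  sess <- generate_chessboard_session(20, 4, scene_config(), seed = 5)
  model <- fit_scale_model(chessboard_observations(sess$annotations))
  path <- withr::local_tempfile(fileext = ".json")
  write_scale_model(model, path, rig = default_rig())
  m2 <- read_scale_model(path)
  q <- seq(150, 550, length.out = 40)
  expect_equal(predict_scale(m2, q, warn = FALSE),
               predict_scale(model, q, warn = FALSE))
  expect_equal(m2$r_squared, model$r_squared)
  expect_identical(m2$rig_hash, rig_hash(default_rig()))

  # tidy/glance surface the coefficients and diagnostics
  td <- tidy(model)
  expect_equal(td$term, paste0("translation^", 0:3))
  gl <- glance(model)
  expect_equal(gl$nobs, 80)
})
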