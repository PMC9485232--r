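#' Chessboard calibration target specification
#'
#' The planar pattern used for empirical scale calibration: a 270 x 190 mm
#' board of 27 x 27 mm squares with corners of 15 squares marked.
#'
#' @param square_size_mm Side of one square in mm.
#' @param board_size_mm Board dimensions `c(width, height)` in mm.
#' @param marked_squares Number of squares whose corners are marked.
#' @return An object of class `chessboard_spec`.
#' @export
chessboard_spec <- function(square_size_mm = 27,
                            board_size_mm = c(270, 190),
                            marked_squares = 15) {
  stopifnot(square_size_mm > 0, all(board_size_mm > 0))
  structure(list(square_size_mm = square_size_mm,
                 board_size_mm = board_size_mm,
                 marked_squares = marked_squares),
            class = "chessboard_spec")
}

#' Derive calibration observations from chessboard stereo annotations
#'
#' Each landmark pair (two marked corners a known integer number of squares
#' apart, annotated in both stereo frames) yields one observation:
#' * `scale` = physical separation (micron) / pixel separation in the
#'   reference frame, and
#' * `translation` = mean of the two endpoints' stereo disparities.
#'
#' Pairs with missing endpoint/frame records are skipped with a warning;
#' pairs with zero pixel separation are rejected.
#'
#' @param annotations Data frame with columns `session_id`, `pose_id`,
#'   `pair_id`, `endpoint` (1|2), `frame` ("a"|"b"), `u`, `v`,
#'   `squares_spanned`.
#' @param spec A [chessboard_spec()].
#' @param reference_frame Frame in which the pixel separation of a pair is
#'   measured: `"a"` (upper camera, default), `"b"`, or `"mean"` of both.
#' @param translation_type Disparity definition, `"euclidean"` (default) or
#'   `"vertical"`; see [px_disparity()].
#' @return A tibble with one row per pair: `session_id`, `pose_id`,
#'   `pair_id`, `translation` (px), `scale` (micron/pixel).
#' @export
chessboard_observations <- function(annotations,
                                    spec = chessboard_spec(),
                                    reference_frame = c("a", "b", "mean"),
                                    translation_type = c("euclidean", "vertical")) {
  reference_frame <- match.arg(reference_frame)
  translation_type <- match.arg(translation_type)
  required <- c("session_id", "pose_id", "pair_id", "endpoint", "frame",
                "u", "v", "squares_spanned")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols) > 0) {
    stop("annotations are missing columns: ", paste(missing_cols, collapse = ", "))
  }

  wide <- annotations |>
    dplyr::mutate(slot = paste0(.data$frame, .data$endpoint)) |>
    tidyr::pivot_wider(
      id_cols = c("session_id", "pose_id", "pair_id", "squares_spanned"),
      names_from = "slot", values_from = c("u", "v")
    )

  needed <- c(t(outer(c("u_", "v_"), c("a1", "a2", "b1", "b2"), paste0)))
  for (col in setdiff(needed, names(wide))) wide[[col]] <- NA_real_
  complete <- stats::complete.cases(wide[needed])
  if (any(!complete)) {
    warning(sprintf("skipping %d pair(s) with missing stereo correspondences",
                    sum(!complete)))
    wide <- wide[complete, , drop = FALSE]
  }

  sep_px <- function(fr) {
    px_disparity(wide[[paste0("u_", fr, "1")]], wide[[paste0("v_", fr, "1")]],
                 wide[[paste0("u_", fr, "2")]], wide[[paste0("v_", fr, "2")]])
  }
  pixel_sep <- switch(reference_frame,
    a = sep_px("a"),
    b = sep_px("b"),
    mean = (sep_px("a") + sep_px("b")) / 2
  )
  d1 <- px_disparity(wide$u_a1, wide$v_a1, wide$u_b1, wide$v_b1,
                     type = translation_type)
  d2 <- px_disparity(wide$u_a2, wide$v_a2, wide$u_b2, wide$v_b2,
                     type = translation_type)

  out <- tibble::tibble(
    session_id = wide$session_id,
    pose_id = wide$pose_id,
    pair_id = wide$pair_id,
    translation = (d1 + d2) / 2,
    scale = wide$squares_spanned * spec$square_size_mm * 1000 / pixel_sep
  )
  bad <- !is.finite(out$scale) | pixel_sep <= 0
  if (any(bad)) {
    warning(sprintf("rejecting %d pair(s) with zero/degenerate pixel separation",
                    sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

poly_design <- function(t_std, degree) {
  outer(t_std, seq_len(degree), `^`)
}

#' Fit the translation-to-scale calibration model
#'
#' Fits micron/pixel scale as a polynomial in landmark translation (pixels)
#' by penalized least squares: polynomial features of the standardized
#' translation with an unpenalized intercept and ridge penalty `lambda` on
#' the polynomial terms. `lambda = 0` reproduces the ordinary cubic
#' polynomial fit; a positive `lambda` gives the polynomial ridge variant.
#'
#' @param observations Data frame with numeric columns `translation` and
#'   `scale` (e.g. from [chessboard_observations()]).
#' @param degree Polynomial degree (default 3, the cubic model).
#' @param lambda Ridge penalty on standardized polynomial features
#'   (default 0 = plain least squares).
#' @param min_translation Lower bound of the model's validity range in
#'   pixels; predictions below it are flagged as extrapolation.
#' @param weights `"none"` (default, plain least squares on the scale) or
#'   `"relative"` (observations weighted by 1 / scale^2, so the fit
#'   minimizes relative rather than absolute residuals — useful when the
#'   downstream error metric is a percentage).
#' @return An object of class `scale_model` with elements `degree`,
#'   `coefficients` (raw-translation basis, lowest order first), `lambda`,
#'   `valid_range`, `r_squared`, `sigma`, `n_obs`, and the training data.
#' @export
fit_scale_model <- function(observations, degree = 3, lambda = 0,
                            min_translation = 140,
                            weights = c("none", "relative")) {
  stopifnot(degree >= 1, lambda >= 0)
  weights <- match.arg(weights)
  t_raw <- as.numeric(observations$translation)
  y <- as.numeric(observations$scale)
  ok <- is.finite(t_raw) & is.finite(y)
  t_raw <- t_raw[ok]; y <- y[ok]
  n <- length(y)
  if (n < degree + 2) {
    stop(sprintf("need at least %d observations to fit degree %d (got %d)",
                 degree + 2, degree, n))
  }
  if (diff(range(t_raw)) == 0) stop("all translations identical: rank-deficient fit")

  center <- mean(t_raw)
  spread <- stats::sd(t_raw)
  t_std <- (t_raw - center) / spread
  X <- poly_design(t_std, degree)
  w <- if (weights == "relative") 1 / y^2 else rep(1, n)

  if (lambda == 0) {
    fit <- stats::lm.wfit(cbind(1, X), y, w)
    beta <- fit$coefficients
    if (anyNA(beta)) stop("rank-deficient polynomial design")
  } else {
    # weighted ridge normal equations with an unpenalized intercept:
    # centre y and X in the weighted mean so only the polynomial terms shrink
    y0 <- stats::weighted.mean(y, w)
    xbar <- apply(X, 2, stats::weighted.mean, w = w)
    Xc <- sweep(X, 2, xbar)
    A <- crossprod(Xc, Xc * w) + diag(lambda, degree)
    b_coef <- solve(A, crossprod(Xc, (y - y0) * w))
    beta0 <- y0 - xbar %*% b_coef
    beta <- c(beta0, b_coef)
  }
  beta <- as.numeric(beta)

  pred <- as.numeric(cbind(1, X) %*% beta)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  sigma <- sqrt(ss_res / max(1, n - degree - 1))

  model <- structure(
    list(
      degree = degree,
      coef_std = beta,
      center = center,
      spread = spread,
      coefficients = standardized_to_raw(beta, center, spread),
      lambda = lambda,
      valid_range = c(min_translation, max(t_raw)),
      r_squared = r2,
      r_squared_defined = ss_tot > 0,
      sigma = sigma,
      n_obs = n,
      data = tibble::tibble(translation = t_raw, scale = y, fitted = pred)
    ),
    class = "scale_model"
  )

  grid <- seq(model$valid_range[1], model$valid_range[2], length.out = 256)
  g <- predict_scale(model, grid, warn = FALSE)
  if (any(g <= 0)) {
    warning("fitted scale model is not strictly positive across its valid range")
  }
  model
}

# expand sum_j beta_j ((t - m)/s)^j into raw powers of t, lowest order first
standardized_to_raw <- function(beta, center, spread) {
  degree <- length(beta) - 1
  raw <- numeric(degree + 1)
  raw[1] <- beta[1]
  for (j in seq_len(degree)) {
    # beta_j / s^j * (t - m)^j expanded binomially
    for (k in 0:j) {
      raw[k + 1] <- raw[k + 1] +
        beta[j + 1] / spread^j * choose(j, k) * (-center)^(j - k)
    }
  }
  raw
}

#' Predict micron/pixel scale at given translations
#'
#' Evaluates the fitted calibration polynomial. Queries outside the model's
#' validity range are still evaluated (field disparities can slightly exceed
#' the calibrated range) but trigger a warning; use
#' [scale_in_range()] to obtain the flag programmatically.
#'
#' @param model A fitted [fit_scale_model()] object.
#' @param translation Numeric vector of translations in pixels.
#' @param warn Warn on out-of-range queries (default TRUE).
#' @return Numeric vector of scales in micron/pixel.
#' @export
predict_scale <- function(model, translation, warn = TRUE) {
  if (!inherits(model, "scale_model")) stop("model is not a fitted scale_model")
  t_std <- (as.numeric(translation) - model$center) / model$spread
  out_of_range <- !scale_in_range(model, translation)
  if (warn && any(out_of_range, na.rm = TRUE)) {
    warning(sprintf("%d translation(s) outside the calibrated range [%.1f, %.1f] px: extrapolating",
                    sum(out_of_range, na.rm = TRUE),
                    model$valid_range[1], model$valid_range[2]))
  }
  as.numeric(cbind(1, poly_design(t_std, model$degree)) %*% model$coef_std)
}

#' @rdname predict_scale
#' @export
scale_in_range <- function(model, translation) {
  translation >= model$valid_range[1] & translation <= model$valid_range[2]
}

#' Coefficient of determination of predictions against observations
#'
#' `1 - SS_res / SS_tot`. With a constant response the statistic is
#' undefined and returned as `NA` with a warning rather than 0.
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 2).
#' @return A single numeric value (possibly `NA`).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("constant observed values: R^2 is undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("Translation -> scale calibration (degree %d, lambda = %g)\n",
              x$degree, x$lambda))
  cat(sprintf("  n = %d observations, valid range [%.1f, %.1f] px\n",
              x$n_obs, x$valid_range[1], x$valid_range[2]))
  r2 <- if (isTRUE(x$r_squared_defined)) sprintf("%.4f", x$r_squared) else "undefined"
  cat(sprintf("  R^2 = %s, residual sigma = %.2f micron/px\n", r2, x$sigma))
  invisible(x)
}

#' Tidy and summarize a scale model
#'
#' `tidy()` returns one row per polynomial coefficient (raw translation
#' basis, lowest order first); `glance()` returns one-row fit diagnostics.
#'
#' @param x A `scale_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.scale_model <- function(x, ...) {
  tibble::tibble(
    term = paste0("translation^", 0:x$degree),
    estimate = x$coefficients
  )
}

#' @rdname tidy.scale_model
#' @export
glance.scale_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$sigma,
    lambda = x$lambda,
    degree = x$degree,
    nobs = x$n_obs,
    range_min = x$valid_range[1],
    range_max = x$valid_range[2]
  )
}

#' Plot a fitted calibration curve
#'
#' Scatter of the training observations with the fitted polynomial and an
#' approximate 95% pointwise prediction band derived from the residual
#' standard deviation.
#'
#' @param object A `scale_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scale_model <- function(object, ...) {
  grid <- tibble::tibble(
    translation = seq(object$valid_range[1], object$valid_range[2],
                      length.out = 200)
  )
  grid$scale <- predict_scale(object, grid$translation, warn = FALSE)
  grid$lo <- grid$scale - 1.96 * object$sigma
  grid$hi <- grid$scale + 1.96 * object$sigma
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$translation, y = .data$scale)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "Landmark translation (pixels)",
                  y = "Scale (micron/pixel)",
                  title = "Chessboard translation-scale calibration",
                  subtitle = sprintf("degree %d, lambda = %g, R² = %.3f",
                                     object$degree, object$lambda,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Serialize / load a scale model as JSON
#'
#' Stores the raw-basis coefficients (lowest order first) together with the
#' standardization constants so that predictions round-trip losslessly.
#'
#' @param model A `scale_model`.
#' @param path File path.
#' @param rig Optional `stereo_rig` whose hash is embedded for provenance.
#' @return `read_scale_model()` returns a `scale_model`; `write_scale_model()`
#'   returns `path` invisibly.
#' @export
write_scale_model <- function(model, path, rig = NULL) {
  stopifnot(inherits(model, "scale_model"))
  obj <- list(
    degree = model$degree,
    coefficients = model$coefficients,
    coef_std = model$coef_std,
    center = model$center,
    spread = model$spread,
    lambda = model$lambda,
    valid_range = model$valid_range,
    r_squared = model$r_squared,
    sigma = model$sigma,
    n_obs = model$n_obs,
    rig_hash = if (!is.null(rig)) rig_hash(rig) else NA
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_scale_model
#' @export
read_scale_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      degree = obj$degree,
      coef_std = obj$coef_std,
      center = obj$center,
      spread = obj$spread,
      coefficients = obj$coefficients,
      lambda = obj$lambda,
      valid_range = obj$valid_range,
      r_squared = obj$r_squared,
      r_squared_defined = !is.null(obj$r_squared) && is.finite(obj$r_squared),
      sigma = obj$sigma,
      n_obs = obj$n_obs,
      rig_hash = obj$rig_hash,
      data = NULL
    ),
    class = "scale_model"
  )
}
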