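#' Fit an allometric length-weight relationship
#'
#' Fits `W = a * L^b` by ordinary least squares of `log(W)` on `log(L)`,
#' the standard linearization for fishery length-weight relationships:
#' `a = exp(intercept)`, `b = slope`. R-squared is reported on the log
#' scale (the scale of the fit). No back-transform bias correction is
#' applied by default; a log-normal correction factor
#' `exp(sigma^2 / 2)` can be switched on.
#'
#' @param data Data frame with length and weight columns (defaults
#'   `standard_length_cm`, `weight_g`), or `NULL` if `lengths`/`weights`
#'   vectors are supplied directly.
#' @param length,weight Column names (tidy-select style strings) when
#'   `data` is given.
#' @param lengths,weights Numeric vectors (cm, g), used when `data` is NULL.
#' @param bias_correction Apply the log-normal back-transform correction to
#'   `a` (default FALSE).
#' @return An object of class `lwr_model` with elements `a`, `b`,
#'   `r_squared`, `sigma`, `n`.
#' @export
fit_lwr <- function(data = NULL, length = "standard_length_cm",
                    weight = "weight_g", lengths = NULL, weights = NULL,
                    bias_correction = FALSE) {
  if (!is.null(data)) {
    lengths <- data[[length]]
    weights <- data[[weight]]
    if (is.null(lengths) || is.null(weights)) {
      stop("columns '", length, "' and '", weight, "' not found in data")
    }
  }
  stopifnot(length(lengths) == length(weights))
  if (length(lengths) < 3) stop("need at least 3 fish to fit the LWR")
  if (any(lengths <= 0) || any(weights <= 0)) {
    stop("lengths and weights must be strictly positive")
  }
  fit <- stats::lm(log(weights) ~ log(lengths))
  cf <- stats::coef(fit)
  sigma <- stats::sigma(fit)
  a <- exp(unname(cf[1]))
  if (bias_correction) a <- a * exp(sigma^2 / 2)
  lw <- log(weights)
  ss_tot <- sum((lw - mean(lw))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(
      a = a,
      b = unname(cf[2]),
      r_squared = r2,
      sigma = sigma,
      n = length(lengths),
      bias_correction = bias_correction
    ),
    class = "lwr_model"
  )
}

#' Predict weight from standard length
#'
#' Evaluates `W = a * L^b` (grams) for the fitted allometric model.
#'
#' @param model An [fit_lwr()] object, or a list with elements `a` and `b`.
#' @param sl Standard length(s) in cm, > 0.
#' @return Numeric vector of weights in grams.
#' @export
predict_weight <- function(model, sl) {
  if (is.null(model$a) || is.null(model$b)) stop("model must provide a and b")
  if (any(!is.finite(sl)) || any(sl <= 0)) stop("standard length must be positive")
  model$a * sl^model$b
}

#' @export
print.lwr_model <- function(x, ...) {
  cat(sprintf("Length-weight relationship: W = %.4f * SL^%.4f\n", x$a, x$b))
  cat(sprintf("  n = %d, R^2 (log scale) = %.3f\n", x$n, x$r_squared))
  invisible(x)
}

#' Tidy and summarize an LWR model
#'
#' @param x An `lwr_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lwr_model <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.lwr_model
#' @export
glance.lwr_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma, nobs = x$n)
}

#' Plot a fitted length-weight curve
#'
#' @param object An `lwr_model`.
#' @param sl_range Length range (cm) for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lwr_model <- function(object, sl_range = c(15, 40), ...) {
  grid <- tibble::tibble(sl = seq(sl_range[1], sl_range[2], length.out = 200))
  grid$w <- predict_weight(object, grid$sl)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$sl, y = .data$w)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "Standard length (cm)", y = "Weight (g)",
                  title = sprintf("W = %.4f · SL^%.4f", object$a, object$b)) +
    ggplot2::theme_minimal()
}

#' Serialize / load an LWR model as JSON
#'
#' @param model An `lwr_model`.
#' @param path File path.
#' @return `read_lwr_model()` returns an `lwr_model`; `write_lwr_model()`
#'   returns `path` invisibly.
#' @export
write_lwr_model <- function(model, path) {
  stopifnot(inherits(model, "lwr_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lwr_model
#' @export
read_lwr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "lwr_model")
}
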