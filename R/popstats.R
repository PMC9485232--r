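#' Percentage difference between sampled and estimated means
#'
#' `|sampled - estimated| / estimated * 100`, the convention used to report
#' the gap between field-sampled and image-estimated mean size. The
#' denominator is the estimated (image-based) mean.
#'
#' @param sampled_mean,estimated_mean Numeric scalars; `estimated_mean > 0`.
#' @param digits Decimal places for reporting; `NULL` returns the exact
#'   value (default 1, the reporting convention).
#' @return Percentage difference.
#' @export
mean_difference_pct <- function(sampled_mean, estimated_mean, digits = NULL) {
  if (!isTRUE(estimated_mean > 0)) stop("estimated_mean must be positive")
  out <- abs(sampled_mean - estimated_mean) / estimated_mean * 100
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' 1-cm size-class histogram
#'
#' Counts in half-open integer-edged bins `[k, k + 1)` cm, labeled by the
#' left edge, covering the data range.
#'
#' @param lengths Numeric vector (n >= 1).
#' @return A tibble with columns `bin` (left edge, cm) and `count`.
#' @export
histogram_1cm <- function(lengths) {
  stopifnot(length(lengths) >= 1, all(is.finite(lengths)))
  left <- floor(lengths)
  bins <- seq(min(left), max(left))
  tibble::tibble(
    bin = bins,
    count = as.integer(vapply(bins, function(b) sum(left == b), integer(1)))
  )
}

#' Matched quantile pairs for a q-q comparison
#'
#' Quantiles of both groups evaluated at the plotting positions of the
#' smaller group (type-7 interpolation). Points on the identity line
#' indicate a common distribution.
#'
#' @param x,y Numeric vectors.
#' @return A tibble with columns `prob`, `q_x`, `q_y`, sorted nondecreasing.
#' @export
qq_pairs <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  probs <- stats::ppoints(min(length(x), length(y)))
  tibble::tibble(
    prob = probs,
    q_x = as.numeric(stats::quantile(x, probs, type = 7, names = FALSE)),
    q_y = as.numeric(stats::quantile(y, probs, type = 7, names = FALSE))
  )
}

#' Compare sampled and estimated size distributions
#'
#' Runs the test cascade used for field validation of image-based sizing:
#' Shapiro-Wilk normality per group, Levene's test for homogeneity of
#' variance across groups (median-centred Brown-Forsythe by default), then a
#' Welch (unequal-variance) F test of mean equality when Levene rejects at
#' `alpha`, or the pooled-variance F test otherwise. Also returns matched
#' q-q quantile pairs and 1-cm histograms for both groups, plus the decision
#' trail.
#'
#' @param sampled,estimated Numeric vectors (each n >= 3); lengths in cm or
#'   weights in g.
#' @param alpha Significance level for the cascade (default 0.05).
#' @param levene_center `"median"` (Brown-Forsythe, default) or `"mean"`.
#' @return An object of class `dist_comparison`.
#' @export
compare_distributions <- function(sampled, estimated, alpha = 0.05,
                                  levene_center = c("median", "mean")) {
  levene_center <- match.arg(levene_center)
  stopifnot(length(sampled) >= 3, length(estimated) >= 3)

  degenerate <- stats::sd(sampled) == 0 || stats::sd(estimated) == 0
  group_stats <- tibble::tibble(
    group = c("sampled", "estimated"),
    n = c(length(sampled), length(estimated)),
    mean = c(mean(sampled), mean(estimated)),
    sd = c(stats::sd(sampled), stats::sd(estimated))
  )

  if (degenerate) {
    shapiro <- levene <- mean_test <- NULL
    decision <- "degenerate (constant group): tests not applicable"
  } else {
    sh_s <- stats::shapiro.test(sampled)
    sh_e <- stats::shapiro.test(estimated)
    shapiro <- tibble::tibble(
      group = c("sampled", "estimated"),
      statistic = c(unname(sh_s$statistic), unname(sh_e$statistic)),
      p.value = c(sh_s$p.value, sh_e$p.value)
    )
    values <- c(sampled, estimated)
    groups <- factor(rep(c("sampled", "estimated"),
                         c(length(sampled), length(estimated))))
    lev <- car::leveneTest(values ~ groups, center = levene_center)
    levene <- tibble::tibble(statistic = lev[1, "F value"],
                             p.value = lev[1, "Pr(>F)"])
    welch_branch <- levene$p.value < alpha
    mt <- stats::oneway.test(values ~ groups, var.equal = !welch_branch)
    mean_test <- tibble::tibble(
      method = if (welch_branch) "welch" else "pooled",
      statistic = unname(mt$statistic),
      df1 = unname(mt$parameter[1]),
      df2 = unname(mt$parameter[2]),
      p.value = mt$p.value
    )
    decision <- paste0(
      "normality: sampled p=", signif(sh_s$p.value, 3),
      ", estimated p=", signif(sh_e$p.value, 3),
      "; Levene (", levene_center, "-centred) p=", signif(levene$p.value, 3),
      if (welch_branch) " < " else " >= ", alpha,
      " -> ", if (welch_branch) "Welch" else "pooled-variance",
      " F test: F=", signif(mean_test$statistic, 4),
      ", p=", signif(mean_test$p.value, 3)
    )
  }

  structure(
    list(
      group_stats = group_stats,
      mean_difference_pct = mean_difference_pct(mean(sampled), mean(estimated)),
      shapiro = shapiro,
      levene = levene,
      mean_test = mean_test,
      qq = qq_pairs(sampled, estimated),
      histogram = dplyr::bind_rows(
        dplyr::mutate(histogram_1cm(sampled), group = "sampled"),
        dplyr::mutate(histogram_1cm(estimated), group = "estimated")
      ),
      alpha = alpha,
      decision = decision
    ),
    class = "dist_comparison"
  )
}

#' @export
print.dist_comparison <- function(x, ...) {
  cat("Distribution comparison\n")
  print(x$group_stats)
  cat(sprintf("  mean difference: %.1f %%\n", x$mean_difference_pct))
  cat(" ", x$decision, "\n")
  invisible(x)
}

#' Tidy and summarize a distribution comparison
#'
#' `tidy()` stacks the test results (one row per test); `glance()` gives
#' one-row group means, SDs and the headline mean test.
#'
#' @param x A `dist_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dist_comparison <- function(x, ...) {
  if (is.null(x$shapiro)) {
    return(tibble::tibble(test = character(), group = character(),
                          statistic = numeric(), p.value = numeric()))
  }
  dplyr::bind_rows(
    dplyr::mutate(x$shapiro, test = "shapiro"),
    dplyr::mutate(x$levene, test = "levene", group = NA_character_),
    tibble::tibble(test = x$mean_test$method,
                   group = NA_character_,
                   statistic = x$mean_test$statistic,
                   p.value = x$mean_test$p.value)
  ) |>
    dplyr::select("test", "group", "statistic", "p.value")
}

#' @rdname tidy.dist_comparison
#' @export
glance.dist_comparison <- function(x, ...) {
  gs <- x$group_stats
  tibble::tibble(
    mean_sampled = gs$mean[gs$group == "sampled"],
    sd_sampled = gs$sd[gs$group == "sampled"],
    mean_estimated = gs$mean[gs$group == "estimated"],
    sd_estimated = gs$sd[gs$group == "estimated"],
    mean_difference_pct = x$mean_difference_pct,
    mean_test = if (is.null(x$mean_test)) NA_character_ else x$mean_test$method,
    statistic = if (is.null(x$mean_test)) NA_real_ else x$mean_test$statistic,
    p.value = if (is.null(x$mean_test)) NA_real_ else x$mean_test$p.value
  )
}

#' Q-q and histogram plots for a distribution comparison
#'
#' @param object A `dist_comparison`.
#' @param type `"qq"` or `"histogram"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dist_comparison <- function(object, type = c("qq", "histogram"), ...) {
  type <- match.arg(type)
  if (type == "qq") {
    ggplot2::ggplot(object$qq, ggplot2::aes(x = .data$q_x, y = .data$q_y)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(colour = "steelblue") +
      ggplot2::labs(x = "Sampled quantiles", y = "Estimated quantiles",
                    title = "Quantile-quantile comparison") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$histogram,
                    ggplot2::aes(x = .data$bin + 0.5, y = .data$count,
                                 fill = .data$group)) +
      ggplot2::geom_col(position = "identity", alpha = 0.5, width = 1) +
      ggplot2::labs(x = "Size class (1-cm bins)", y = "Count", fill = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Write a distribution comparison as JSON
#'
#' @param comparison A `dist_comparison`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  obj <- list(
    group_stats = comparison$group_stats,
    mean_difference_pct = comparison$mean_difference_pct,
    shapiro = comparison$shapiro,
    levene = comparison$levene,
    mean_test = comparison$mean_test,
    qq = comparison$qq,
    histogram = comparison$histogram,
    alpha = comparison$alpha,
    decision = comparison$decision
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
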