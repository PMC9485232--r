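#' Reshape long fish landmark annotations into one row per fish
#'
#' @param annotations Data frame with columns `fish_id`, `frame` ("a"|"b"),
#'   `landmark` ("snout"|"caudal"), `u`, `v`, and optionally `confidence`.
#' @return A tibble with one row per fish and columns
#'   `u_snout_a`, `v_snout_a`, ..., `v_caudal_b` (plus `confidence` if
#'   present).
#' @export
landmark_pairs <- function(annotations) {
  required <- c("fish_id", "frame", "landmark", "u", "v")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols) > 0) {
    stop("annotations are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  has_conf <- "confidence" %in% names(annotations)
  wide <- annotations |>
    dplyr::mutate(slot = paste(.data$landmark, .data$frame, sep = "_")) |>
    tidyr::pivot_wider(id_cols = "fish_id", names_from = "slot",
                       values_from = c("u", "v"),
                       values_fn = function(x) x[1])
  if (has_conf) {
    conf <- annotations |>
      dplyr::summarise(confidence = min(.data$confidence), .by = "fish_id")
    wide <- dplyr::left_join(wide, conf, by = "fish_id")
  }
  wide
}

#' Per-fish landmark translation
#'
#' Mean of the stereo disparities of the snout and caudal landmarks — the
#' same averaging used for chessboard landmark pairs during calibration.
#'
#' @param pairs A wide landmark tibble from [landmark_pairs()].
#' @param type Disparity definition passed to [px_disparity()].
#' @return Numeric vector of translations in pixels, one per fish.
#' @export
fish_translation <- function(pairs, type = c("euclidean", "vertical")) {
  type <- match.arg(type)
  d_snout <- px_disparity(pairs$u_snout_a, pairs$v_snout_a,
                          pairs$u_snout_b, pairs$v_snout_b, type = type)
  d_caudal <- px_disparity(pairs$u_caudal_a, pairs$v_caudal_a,
                           pairs$u_caudal_b, pairs$v_caudal_b, type = type)
  (d_snout + d_caudal) / 2
}

#' Minimum-translation quality filter
#'
#' Fish whose landmark translation falls below the minimum are too distant
#' for a reliable parallax scale and are discarded. The comparison is
#' inclusive: a translation exactly at the threshold passes.
#'
#' @param translation Numeric vector of translations in pixels (>= 0).
#' @param min_translation Threshold in pixels (default 140).
#' @return Logical vector.
#' @export
passes_threshold <- function(translation, min_translation = 140) {
  stopifnot(all(translation >= 0, na.rm = TRUE))
  translation >= min_translation
}

#' Estimate standard lengths from stereo landmark annotations
#'
#' For each fish: pixel length is the snout-caudal pixel distance in the
#' reference (upper) frame; translation is the mean disparity of the two
#' landmarks; the calibrated scale model converts translation to
#' micron/pixel; and standard length (cm) = pixel length x scale / 1e4.
#' Fish failing the minimum-translation filter, or with degenerate
#' landmarks, are flagged `qc_pass = FALSE` with a reason and carry no
#' length.
#'
#' @param annotations Long annotation data frame (see [landmark_pairs()]),
#'   or a wide tibble already in `landmark_pairs()` layout.
#' @param model A fitted [fit_scale_model()] object.
#' @param min_translation Threshold in pixels (default 140).
#' @param translation_type Disparity definition for the translation.
#' @param reference_frame Frame used for the pixel length: `"a"` (default,
#'   matching the calibration reference) or `"mean"` of both frames.
#' @return A tibble with columns `fish_id`, `pixel_length`, `translation`,
#'   `scale`, `standard_length`, `extrapolated`, `qc_pass`, `qc_reason`.
#' @export
estimate_lengths <- function(annotations, model, min_translation = 140,
                             translation_type = c("euclidean", "vertical"),
                             reference_frame = c("a", "mean")) {
  if (!inherits(model, "scale_model")) stop("model is not a fitted scale_model")
  translation_type <- match.arg(translation_type)
  reference_frame <- match.arg(reference_frame)

  pairs <- if ("landmark" %in% names(annotations)) {
    landmark_pairs(annotations)
  } else {
    annotations
  }
  if (nrow(pairs) == 0) {
    return(tibble::tibble(
      fish_id = character(), pixel_length = numeric(),
      translation = numeric(), scale = numeric(),
      standard_length = numeric(), extrapolated = logical(),
      qc_pass = logical(), qc_reason = character()
    ))
  }

  len_a <- px_disparity(pairs$u_snout_a, pairs$v_snout_a,
                        pairs$u_caudal_a, pairs$v_caudal_a)
  pixel_length <- if (reference_frame == "a") {
    len_a
  } else {
    len_b <- px_disparity(pairs$u_snout_b, pairs$v_snout_b,
                          pairs$u_caudal_b, pairs$v_caudal_b)
    (len_a + len_b) / 2
  }
  translation <- fish_translation(pairs, type = translation_type)

  qc_reason <- rep(NA_character_, nrow(pairs))
  qc_pass <- rep(TRUE, nrow(pairs))

  degenerate <- !is.finite(pixel_length) | pixel_length <= 0 |
    !is.finite(translation)
  qc_pass[degenerate] <- FALSE
  qc_reason[degenerate] <- "degenerate landmarks"

  below <- !degenerate & !passes_threshold(translation, min_translation)
  qc_pass[below] <- FALSE
  qc_reason[below] <- sprintf("translation below %g px", min_translation)

  scale <- rep(NA_real_, nrow(pairs))
  standard_length <- rep(NA_real_, nrow(pairs))
  extrapolated <- rep(NA, nrow(pairs))
  if (any(qc_pass)) {
    scale[qc_pass] <- predict_scale(model, translation[qc_pass], warn = FALSE)
    extrapolated[qc_pass] <- !scale_in_range(model, translation[qc_pass])
    standard_length[qc_pass] <- pixel_length[qc_pass] * scale[qc_pass] / 1e4
  }

  tibble::tibble(
    fish_id = pairs$fish_id,
    pixel_length = pixel_length,
    translation = translation,
    scale = scale,
    standard_length = standard_length,
    extrapolated = extrapolated,
    qc_pass = qc_pass,
    qc_reason = qc_reason
  )
}

#' Length-measurement validation report
#'
#' Compares estimated against true lengths of reference targets (e.g. the
#' plastic fish silhouettes of known size) and reports the mean absolute
#' error in cm together with the mean absolute percentage error.
#'
#' @param true_cm Numeric vector of true standard lengths (cm, > 0).
#' @param estimated_cm Numeric vector of estimates, same length.
#' @param ids Optional identifiers for the per-target residual table.
#' @return An object of class `validation_report`: a list with
#'   `n_measurements`, `mae_cm`, `mape_pct`, and a `residuals` tibble.
#' @export
length_validation <- function(true_cm, estimated_cm, ids = NULL) {
  if (length(true_cm) != length(estimated_cm)) {
    stop("true and estimated length vectors must have equal length")
  }
  stopifnot(length(true_cm) >= 1, all(true_cm > 0))
  if (is.null(ids)) ids <- as.character(seq_along(true_cm))
  resid <- tibble::tibble(
    id = ids,
    true_cm = true_cm,
    estimated_cm = estimated_cm,
    error_cm = estimated_cm - true_cm,
    abs_error_cm = abs(estimated_cm - true_cm),
    abs_error_pct = abs(estimated_cm - true_cm) / true_cm * 100
  )
  structure(
    list(
      n_measurements = length(true_cm),
      mae_cm = mean(resid$abs_error_cm),
      mape_pct = mean(resid$abs_error_pct),
      residuals = resid
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Length validation over %d measurements\n", x$n_measurements))
  cat(sprintf("  mean absolute error: %.2f cm\n", x$mae_cm))
  cat(sprintf("  mean absolute percentage error: %.2f %%\n", x$mape_pct))
  invisible(x)
}

#' @rdname length_validation
#' @param x A `validation_report`.
#' @param ... Unused.
#' @export
tidy.validation_report <- function(x, ...) x$residuals

#' @rdname length_validation
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(n = x$n_measurements, mae_cm = x$mae_cm, mape_pct = x$mape_pct)
}

#' Write a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    list(n_measurements = report$n_measurements,
         mae_cm = report$mae_cm,
         mape_pct = report$mape_pct,
         residuals = report$residuals),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
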