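#' Camera intrinsics for a pinhole model
#'
#' Describes one camera of the stereo rig: sensor resolution, focal length
#' expressed in pixels (per axis), principal point and skew. The focal length
#' in pixels can be given directly, derived from a physical focal length and
#' pixel pitch (`f_x = F / p_x`), or derived from the field of view
#' (`f_x = (width/2) / tan(FOV_h/2)`).
#'
#' @param resolution Integer vector `c(width, height)` in pixels.
#' @param fov Field of view `c(horizontal, vertical)` in degrees, used to
#'   derive `focal_px` when the latter is not supplied.
#' @param focal_px Focal length in pixels, `c(f_x, f_y)`. Overrides `fov`.
#' @param focal_length_mm Physical focal length F in mm (used with
#'   `pixel_size_mm`).
#' @param pixel_size_mm Pixel pitch `c(p_x, p_y)` in mm/pixel.
#' @param principal_point Optical centre `c(c_x, c_y)` in pixels; defaults to
#'   the image centre.
#' @param skew Skew coefficient `s` (non-zero only if the image axes are not
#'   perpendicular); `s = f_x * tan(alpha)`. Default 0.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(resolution = c(3280, 2464),
                              fov = c(54, 41),
                              focal_px = NULL,
                              focal_length_mm = NULL,
                              pixel_size_mm = NULL,
                              principal_point = resolution / 2,
                              skew = 0) {
  stopifnot(length(resolution) == 2, all(resolution > 0))
  if (is.null(focal_px)) {
    if (!is.null(focal_length_mm) && !is.null(pixel_size_mm)) {
      focal_px <- focal_length_mm / rep_len(pixel_size_mm, 2)
    } else {
      stopifnot(length(fov) == 2, all(fov > 0), all(fov < 180))
      focal_px <- (resolution / 2) / tan(fov * pi / 360)
    }
  }
  focal_px <- rep_len(as.numeric(focal_px), 2)
  if (any(!is.finite(focal_px)) || any(focal_px <= 0)) {
    stop("focal_px must be positive and finite")
  }
  pp <- rep_len(as.numeric(principal_point), 2)
  if (pp[1] < 0 || pp[1] >= resolution[1] || pp[2] < 0 || pp[2] >= resolution[2]) {
    stop("principal_point must lie within the sensor")
  }
  structure(
    list(
      resolution = as.numeric(resolution),
      focal_px = focal_px,
      principal_point = pp,
      skew = as.numeric(skew),
      fov = if (!is.null(fov)) as.numeric(fov) else NULL,
      focal_length_mm = focal_length_mm,
      pixel_size_mm = pixel_size_mm
    ),
    class = "camera_intrinsics"
  )
}

#' Brown radial distortion coefficients
#'
#' Two-coefficient radial model on normalized image coordinates:
#' `x_d = x_u * (1 + k1 * r^2 + k2 * r^4)`. `(0, 0)` is the identity.
#'
#' @param k1,k2 Dimensionless radial coefficients.
#' @return An object of class `radial_distortion`.
#' @export
radial_distortion <- function(k1 = 0, k2 = 0) {
  stopifnot(is.finite(k1), is.finite(k2))
  structure(list(k1 = as.numeric(k1), k2 = as.numeric(k2)),
            class = "radial_distortion")
}

#' Stereo rig geometry
#'
#' Two pinhole cameras separated by a vertical baseline. Camera `a` is the
#' upper (reference) camera; camera `b` sits `baseline` metres below it along
#' the world y axis. `medium_index` is an empirical refractive scaling applied
#' multiplicatively to the focal length in pixels (1.0 in air, ~1.33 as a flat
#' approximation in water); refraction is otherwise absorbed by the empirical
#' chessboard calibration, not ray-traced.
#'
#' @param camera_a,camera_b [camera_intrinsics()] objects; both cameras must
#'   share the sensor resolution.
#' @param baseline Lens separation in metres (default 0.08, vertical axis).
#' @param distortion A [radial_distortion()] object shared by both cameras.
#' @param medium_index Dimensionless focal scaling for the imaging medium.
#' @return An object of class `stereo_rig`.
#' @export
stereo_rig <- function(camera_a = camera_intrinsics(),
                       camera_b = camera_a,
                       baseline = 0.08,
                       distortion = radial_distortion(),
                       medium_index = 1.0) {
  stopifnot(inherits(camera_a, "camera_intrinsics"),
            inherits(camera_b, "camera_intrinsics"),
            inherits(distortion, "radial_distortion"))
  if (!isTRUE(baseline > 0)) stop("baseline must be positive")
  if (!identical(camera_a$resolution, camera_b$resolution)) {
    stop("both cameras must share the sensor resolution")
  }
  stopifnot(medium_index > 0)
  structure(
    list(camera_a = camera_a, camera_b = camera_b,
         baseline = as.numeric(baseline),
         distortion = distortion,
         medium_index = as.numeric(medium_index)),
    class = "stereo_rig"
  )
}

#' Default buoy stereo rig
#'
#' The 8-MP rig used throughout: two 3280 x 2464 cameras with a 54 deg
#' horizontal field of view, 8 cm vertical baseline. Square pixels are
#' assumed, so a single focal length (3218.68 px, derived from the horizontal
#' FOV) serves both axes; the implied vertical FOV is 41.9 deg, matching the
#' nominal 41 deg to within rounding.
#'
#' @param baseline Baseline in metres.
#' @param k1,k2 Radial distortion coefficients.
#' @param medium_index Refractive focal scaling (1 = air).
#' @return A `stereo_rig`.
#' @export
default_rig <- function(baseline = 0.08, k1 = 0, k2 = 0, medium_index = 1.0) {
  f <- (3280 / 2) / tan(54 * pi / 360)
  cam <- camera_intrinsics(resolution = c(3280, 2464), fov = c(54, 41),
                           focal_px = c(f, f))
  stereo_rig(cam, cam, baseline = baseline,
             distortion = radial_distortion(k1, k2),
             medium_index = medium_index)
}

effective_focal <- function(cam, rig) cam$focal_px * rig$medium_index

#' Project world points into a camera of the rig
#'
#' Standard pinhole projection `u = f_x * (x/z) + s * (y/z) + c_x`,
#' `v = f_y * (y'/z) + c_y`, where `y'` is `y` shifted by the baseline for
#' camera `b`. Radial distortion is applied afterwards when non-zero.
#'
#' @param points A data frame with columns `x`, `y`, `z` (metres,
#'   camera-a frame, z along the optical axis).
#' @param rig A [stereo_rig()].
#' @param camera `"a"` (upper, reference) or `"b"` (lower).
#' @return A tibble with columns `u`, `v` (pixels; origin top-left, x right,
#'   y down).
#' @export
project_points <- function(points, rig, camera = c("a", "b")) {
  camera <- match.arg(camera)
  stopifnot(inherits(rig, "stereo_rig"),
            all(c("x", "y", "z") %in% names(points)))
  x <- as.numeric(points$x); y <- as.numeric(points$y); z <- as.numeric(points$z)
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop("projection requires z > 0 for every point")
  }
  cam <- if (camera == "a") rig$camera_a else rig$camera_b
  if (camera == "b") y <- y - rig$baseline
  f <- effective_focal(cam, rig)
  u <- f[1] * (x / z) + cam$skew * (y / z) + cam$principal_point[1]
  v <- f[2] * (y / z) + cam$principal_point[2]
  out <- tibble::tibble(u = u, v = v)
  if (rig$distortion$k1 != 0 || rig$distortion$k2 != 0) {
    out <- apply_distortion(out, cam, rig$distortion, focal_scale = rig$medium_index)
  }
  out
}

normalize_px <- function(points, cam, focal_scale = 1) {
  f <- cam$focal_px * focal_scale
  tibble::tibble(
    x = (points$u - cam$principal_point[1]) / f[1],
    y = (points$v - cam$principal_point[2]) / f[2]
  )
}

denormalize_px <- function(norm, cam, focal_scale = 1) {
  f <- cam$focal_px * focal_scale
  tibble::tibble(
    u = norm$x * f[1] + cam$principal_point[1],
    v = norm$y * f[2] + cam$principal_point[2]
  )
}

#' Apply Brown radial distortion to pixel points
#'
#' @param points Data frame with `u`, `v` columns (pixels, undistorted).
#' @param cam A [camera_intrinsics()].
#' @param distortion A [radial_distortion()].
#' @param focal_scale Optional focal scaling (e.g. a rig's `medium_index`).
#' @return Tibble of distorted `u`, `v`.
#' @export
apply_distortion <- function(points, cam, distortion, focal_scale = 1) {
  stopifnot(all(is.finite(points$u)), all(is.finite(points$v)))
  n <- normalize_px(points, cam, focal_scale)
  r2 <- n$x^2 + n$y^2
  fac <- 1 + distortion$k1 * r2 + distortion$k2 * r2^2
  denormalize_px(tibble::tibble(x = n$x * fac, y = n$y * fac), cam, focal_scale)
}

#' Invert radial distortion numerically
#'
#' Fixed-point iteration on the undistorted normalized radius; converges for
#' the moderate distortions of this rig (|k1| <= 0.3 within the unit radius).
#' The round trip `undistort(apply_distortion(p))` returns `p` within
#' 1e-6 px.
#'
#' @inheritParams apply_distortion
#' @param max_iter,tol Iteration controls on normalized coordinates.
#' @return Tibble of undistorted `u`, `v`.
#' @export
undistort <- function(points, cam, distortion, focal_scale = 1,
                      max_iter = 100L, tol = 1e-12) {
  stopifnot(all(is.finite(points$u)), all(is.finite(points$v)))
  d <- normalize_px(points, cam, focal_scale)
  xu <- d$x; yu <- d$y
  for (i in seq_len(max_iter)) {
    r2 <- xu^2 + yu^2
    fac <- 1 + distortion$k1 * r2 + distortion$k2 * r2^2
    x_new <- d$x / fac
    y_new <- d$y / fac
    delta <- max(abs(x_new - xu), abs(y_new - yu))
    xu <- x_new; yu <- y_new
    if (delta < tol) break
  }
  r2 <- xu^2 + yu^2
  fac <- 1 + distortion$k1 * r2 + distortion$k2 * r2^2
  resid <- max(abs(xu * fac - d$x), abs(yu * fac - d$y))
  if (!is.finite(resid) || resid > 1e-8) {
    stop(sprintf("undistortion failed to converge (residual %.3g normalized units)",
                 resid))
  }
  denormalize_px(tibble::tibble(x = xu, y = yu), cam, focal_scale)
}

#' Pixel disparity (translation) between corresponding stereo points
#'
#' Euclidean pixel distance between the same physical point seen in the two
#' stereo frames. For the vertical-baseline rig the vertical component
#' dominates. Also used for within-frame pixel distances (e.g. snout-caudal
#' length).
#'
#' @param u_a,v_a,u_b,v_b Pixel coordinates in frames a and b (vectorized).
#' @param type `"euclidean"` (default) or `"vertical"` (|v_b - v_a| only).
#' @return Numeric vector of disparities in pixels (>= 0).
#' @export
px_disparity <- function(u_a, v_a, u_b, v_b, type = c("euclidean", "vertical")) {
  type <- match.arg(type)
  stopifnot(all(is.finite(c(u_a, v_a, u_b, v_b))))
  if (type == "vertical") abs(v_b - v_a) else sqrt((u_b - u_a)^2 + (v_b - v_a)^2)
}

#' Analytic parallax scale at a given disparity
#'
#' For an aligned rig the metric scale at the target's depth is
#' `baseline * 1e6 / disparity` micron/pixel, independent of the focal
#' length: disparity `d = f * B / z` and scale `z * 1e6 / f` cancel `f`.
#' This is the analytic oracle that the empirical chessboard calibration
#' approximates.
#'
#' @param disparity Pixel disparity (> 0), vectorized.
#' @param rig A [stereo_rig()], or `baseline` given directly.
#' @param baseline Baseline in metres (overrides `rig`).
#' @return Scale in micron/pixel.
#' @export
ideal_scale_from_disparity <- function(disparity, rig = NULL, baseline = NULL) {
  if (is.null(baseline)) {
    if (is.null(rig)) stop("supply a rig or a baseline")
    baseline <- rig$baseline
  }
  if (any(!is.finite(disparity)) || any(disparity <= 0)) {
    stop("disparity must be positive")
  }
  baseline * 1e6 / disparity
}

#' Serialize / load a stereo rig as JSON
#'
#' @param rig A [stereo_rig()].
#' @param path File path.
#' @return `read_rig()` returns a `stereo_rig`; `write_rig()` returns `path`
#'   invisibly.
#' @export
write_rig <- function(rig, path) {
  stopifnot(inherits(rig, "stereo_rig"))
  cam_list <- function(cam) {
    list(resolution = cam$resolution, focal_px = cam$focal_px,
         principal_point = cam$principal_point, skew = cam$skew)
  }
  obj <- list(
    camera_a = cam_list(rig$camera_a),
    camera_b = cam_list(rig$camera_b),
    baseline_m = rig$baseline,
    distortion = list(k1 = rig$distortion$k1, k2 = rig$distortion$k2),
    medium_index = rig$medium_index
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rig
#' @export
read_rig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cam_from <- function(x) {
    camera_intrinsics(resolution = x$resolution, focal_px = x$focal_px,
                      principal_point = x$principal_point, skew = x$skew,
                      fov = NULL)
  }
  stereo_rig(cam_from(obj$camera_a), cam_from(obj$camera_b),
             baseline = obj$baseline_m,
             distortion = radial_distortion(obj$distortion$k1, obj$distortion$k2),
             medium_index = obj$medium_index)
}

#' Stable content hash of a rig definition
#'
#' FNV-1a hash of the canonical JSON serialization, used to tie a fitted
#' scale model to the rig it was calibrated for.
#'
#' @param rig A `stereo_rig`.
#' @return An 8-hex-digit character scalar.
#' @export
rig_hash <- function(rig) {
  # fixed-precision formatting so the hash survives JSON serialization,
  # which preserves doubles only to ~15 significant digits
  vals <- c(rig$camera_a$focal_px, rig$camera_b$focal_px,
            rig$camera_a$principal_point, rig$camera_b$principal_point,
            rig$camera_a$resolution, rig$camera_a$skew, rig$camera_b$skew,
            rig$baseline, rig$distortion$k1, rig$distortion$k2,
            rig$medium_index)
  fnv1a(paste(sprintf("%.9e", vals), collapse = "|"))
}

fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply, split to stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
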