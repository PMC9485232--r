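#' Synthetic stereo-scene configuration
#'
#' Bundles the rig and acquisition parameters that every scene generator
#' shares. Landmark jitter emulates the pixel-level error of the landmark
#' detector; 2 px is the default stand-in (no pixel-scale detector error is
#' published for the rig, so this is a documented modeling knob).
#'
#' @param rig A [stereo_rig()] (default [default_rig()]).
#' @param distance_range Target distances in metres, ordered (default
#'   `c(0.3, 2.0)`, which straddles the 140-px disparity threshold on the
#'   default rig).
#' @param landmark_jitter_sd Gaussian jitter SD added to every landmark
#'   pixel coordinate (default 2).
#' @param yaw_sd SD of fish yaw in degrees (0 = fronto-parallel validation
#'   geometry; > 0 emulates free-swimming pose foreshortening).
#' @param min_translation Disparity threshold used to flag fish expected to
#'   fail quality control (default 140 px).
#' @param seed Integer seed for reproducibility (optional; generators also
#'   accept a seed directly).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(rig = default_rig(),
                         distance_range = c(0.3, 2.0),
                         landmark_jitter_sd = 2.0,
                         yaw_sd = 0,
                         min_translation = 140,
                         seed = NULL) {
  stopifnot(inherits(rig, "stereo_rig"),
            length(distance_range) == 2,
            distance_range[1] > 0,
            distance_range[1] <= distance_range[2],
            landmark_jitter_sd >= 0, yaw_sd >= 0)
  structure(
    list(rig = rig, distance_range = distance_range,
         landmark_jitter_sd = landmark_jitter_sd, yaw_sd = yaw_sd,
         min_translation = min_translation, seed = seed),
    class = "scene_config"
  )
}

#' Synthetic fish-population configuration
#'
#' Defaults parameterize the reference farmed-seabream cage population:
#' 190 fish, standard length Normal(27.1, 1.6) cm, weights from the
#' allometric model W = 0.1342 * SL^2.5465 with multiplicative log-normal
#' noise (CV 0.08, which together with the length spread reproduces the
#' observed weight dispersion of roughly 103 g around 606 g).
#'
#' @param n Number of fish.
#' @param sl_mean,sl_sd Standard-length distribution (cm).
#' @param lwr_a,lwr_b Allometric coefficients.
#' @param weight_noise_cv Coefficient of variation of the multiplicative
#'   weight noise (0 = exact power law).
#' @param seed Integer seed (optional).
#' @return An object of class `population_config`.
#' @export
population_config <- function(n = 190, sl_mean = 27.1, sl_sd = 1.6,
                              lwr_a = 0.1342, lwr_b = 2.5465,
                              weight_noise_cv = 0.08, seed = NULL) {
  stopifnot(n >= 1, sl_mean > 0, sl_sd > 0, lwr_a > 0, weight_noise_cv >= 0)
  structure(
    list(n = n, sl_mean = sl_mean, sl_sd = sl_sd,
         lwr_a = lwr_a, lwr_b = lwr_b,
         weight_noise_cv = weight_noise_cv, seed = seed),
    class = "population_config"
  )
}

# evaluate code under a temporary RNG state when seed is given
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

vertical_focal_a <- function(rig) effective_focal(rig$camera_a, rig)[2]

project_landmark_rows <- function(points, rig, jitter_sd) {
  pa <- project_points(points, rig, "a")
  pb <- project_points(points, rig, "b")
  n <- nrow(points)
  if (jitter_sd > 0) {
    pa$u <- pa$u + stats::rnorm(n, 0, jitter_sd)
    pa$v <- pa$v + stats::rnorm(n, 0, jitter_sd)
    pb$u <- pb$u + stats::rnorm(n, 0, jitter_sd)
    pb$v <- pb$v + stats::rnorm(n, 0, jitter_sd)
  }
  list(a = pa, b = pb)
}

#' Generate a synthetic chessboard calibration session
#'
#' Emulates the calibration protocol: a chessboard is posed at varying
#' distances in front of the vertical-baseline rig, and on each pose
#' several landmark pairs (marked corners a known number of squares apart)
#' are annotated in both stereo frames. Pose distances are drawn so that
#' landmark disparities cover `disparity_range` uniformly. With zero jitter
#' and zero distortion, the derived observations fall exactly on the
#' parallax hyperbola `scale = baseline * 1e6 / disparity`.
#'
#' @param n_poses Number of board poses (stereo image pairs); default 52.
#' @param pairs_per_pose Landmark pairs annotated per pose; default 4.
#' @param cfg A [scene_config()].
#' @param spec A [chessboard_spec()].
#' @param disparity_range Pixel-disparity interval covered by the poses.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A list with `annotations` (calibration CSV dialect: `session_id`,
#'   `pose_id`, `pair_id`, `endpoint`, `frame`, `u`, `v`, `squares_spanned`)
#'   and `truth` (`pose_id`, `distance_m`, `true_scale`,
#'   `expected_translation`).
#' @export
generate_chessboard_session <- function(n_poses = 52, pairs_per_pose = 4,
                                        cfg = scene_config(),
                                        spec = chessboard_spec(),
                                        disparity_range = c(150, 600),
                                        seed = cfg$seed) {
  stopifnot(n_poses >= 2, pairs_per_pose >= 1)
  with_local_seed(seed, {
    rig <- cfg$rig
    f <- vertical_focal_a(rig)
    f_x <- effective_focal(rig$camera_a, rig)[1]
    disp <- stats::runif(n_poses, disparity_range[1], disparity_range[2])
    z <- f * rig$baseline / disp

    rows <- vector("list", n_poses)
    truth <- tibble::tibble(
      pose_id = sprintf("pose%02d", seq_len(n_poses)),
      distance_m = z,
      true_scale = z * 1e6 / f_x,
      expected_translation = disp
    )
    sq_m <- spec$square_size_mm / 1000
    half_w <- spec$board_size_mm[1] / 2000
    half_h <- spec$board_size_mm[2] / 2000

    for (i in seq_len(n_poses)) {
      # board centre offset keeps the whole board comfortably in frame
      cx <- stats::runif(1, -0.08, 0.08) * z[i]
      cy <- stats::runif(1, -0.05, 0.05) * z[i]
      spans <- sample(2:6, pairs_per_pose, replace = TRUE)
      theta <- stats::runif(pairs_per_pose, 0, 2 * pi)
      len <- spans * sq_m
      px <- stats::runif(pairs_per_pose, -half_w + max(len) / 2,
                         half_w - max(len) / 2)
      py <- stats::runif(pairs_per_pose, -half_h + max(len) / 2,
                         half_h - max(len) / 2)
      pts <- tibble::tibble(
        x = cx + rep(px, each = 2) +
          rep(c(-0.5, 0.5), pairs_per_pose) * rep(len * cos(theta), each = 2),
        y = cy + rep(py, each = 2) +
          rep(c(-0.5, 0.5), pairs_per_pose) * rep(len * sin(theta), each = 2),
        z = z[i]
      )
      proj <- project_landmark_rows(pts, rig, cfg$landmark_jitter_sd)
      base <- tibble::tibble(
        session_id = "synthetic",
        pose_id = truth$pose_id[i],
        pair_id = rep(sprintf("p%d", seq_len(pairs_per_pose)), each = 2),
        endpoint = rep(1:2, pairs_per_pose),
        squares_spanned = rep(spans, each = 2)
      )
      rows[[i]] <- dplyr::bind_rows(
        dplyr::mutate(base, frame = "a", u = proj$a$u, v = proj$a$v),
        dplyr::mutate(base, frame = "b", u = proj$b$u, v = proj$b$v)
      )
    }
    list(
      annotations = dplyr::bind_rows(rows) |>
        dplyr::select("session_id", "pose_id", "pair_id", "endpoint",
                      "frame", "u", "v", "squares_spanned"),
      truth = truth
    )
  })
}

#' Generate a synthetic silhouette validation set
#'
#' Emulates the measurement-error protocol: rigid fish silhouettes of known
#' standard length are photographed fronto-parallel at increasing distances
#' from the rig, every image containing all silhouettes. Distances are
#' chosen so the landmark disparities decrease evenly across
#' `disparity_range` as the targets move away.
#'
#' @param lengths True silhouette standard lengths in cm (default the four
#'   reference silhouettes 22.0, 24.2, 29.0, 33.6).
#' @param n_images Number of stereo images (distances); default 17.
#' @param cfg A [scene_config()].
#' @param disparity_range Disparity interval covered by the distances; the
#'   default keeps every target above the 140-px threshold.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A list with `annotations` (fish CSV dialect: `fish_id`, `frame`,
#'   `landmark`, `u`, `v`, `confidence`) and `truth` (`fish_id`,
#'   `true_length_cm`, `distance_m`, `expected_translation`,
#'   `expect_filtered`).
#' @export
generate_silhouette_validation <- function(lengths = c(22.0, 24.2, 29.0, 33.6),
                                           n_images = 17,
                                           cfg = scene_config(),
                                           disparity_range = c(150, 600),
                                           seed = cfg$seed) {
  stopifnot(all(lengths > 0), n_images >= 1)
  with_local_seed(seed, {
    rig <- cfg$rig
    f <- vertical_focal_a(rig)
    disp <- seq(disparity_range[2], disparity_range[1], length.out = n_images)
    z <- f * rig$baseline / disp
    k <- length(lengths)
    y_off <- seq(-0.12, 0.12, length.out = k)

    ann <- vector("list", n_images)
    truth <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      x0 <- stats::runif(k, -0.05, 0.05) * z[i]
      half <- lengths / 200  # cm -> m, half-length
      pts <- tibble::tibble(
        x = rep(x0, each = 2) + rep(c(-1, 1), k) * rep(half, each = 2),
        y = rep(y_off * z[i], each = 2),
        z = z[i]
      )
      proj <- project_landmark_rows(pts, rig, cfg$landmark_jitter_sd)
      ids <- sprintf("img%02d_s%d", i, seq_len(k))
      base <- tibble::tibble(
        fish_id = rep(ids, each = 2),
        landmark = rep(c("snout", "caudal"), k),
        confidence = 1
      )
      ann[[i]] <- dplyr::bind_rows(
        dplyr::mutate(base, frame = "a", u = proj$a$u, v = proj$a$v),
        dplyr::mutate(base, frame = "b", u = proj$b$u, v = proj$b$v)
      )
      truth[[i]] <- tibble::tibble(
        fish_id = ids,
        true_length_cm = lengths,
        distance_m = z[i],
        expected_translation = disp[i],
        expect_filtered = disp[i] < cfg$min_translation
      )
    }
    list(
      annotations = dplyr::bind_rows(ann) |>
        dplyr::select("fish_id", "frame", "landmark", "u", "v", "confidence"),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Generate a synthetic fish population
#'
#' Standard lengths are Normal(`sl_mean`, `sl_sd`) truncated below at 5 cm;
#' weights follow the allometric power law with mean-one log-normal
#' multiplicative noise of the configured coefficient of variation.
#'
#' @param cfg A [population_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A tibble `fish_id`, `standard_length_cm`, `weight_g`.
#' @export
generate_fish_population <- function(cfg = population_config(),
                                     seed = cfg$seed) {
  with_local_seed(seed, {
    sl <- stats::rnorm(cfg$n, cfg$sl_mean, cfg$sl_sd)
    while (any(sl <= 5)) {
      bad <- sl <= 5
      sl[bad] <- stats::rnorm(sum(bad), cfg$sl_mean, cfg$sl_sd)
    }
    w <- cfg$lwr_a * sl^cfg$lwr_b
    if (cfg$weight_noise_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$weight_noise_cv^2))
      w <- w * stats::rlnorm(cfg$n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tibble::tibble(
      fish_id = sprintf("fish%03d", seq_len(cfg$n)),
      standard_length_cm = sl,
      weight_g = w
    )
  })
}

#' Generate a synthetic free-swimming fish scene
#'
#' Places each fish of a population at a uniform random distance within the
#' configured range, with Gaussian yaw about the fronto-parallel pose, and
#' projects the snout and caudal landmarks into both stereo frames with
#' pixel jitter. Yaw foreshortens the visible length to `SL * cos(yaw)`, so
#' field-emulation scenes reproduce the downward bias and dispersion
#' inflation of uncorrected stereo length estimates. The truth table flags
#' fish whose expected translation falls below the quality threshold.
#'
#' @param population A tibble from [generate_fish_population()] (columns
#'   `fish_id`, `standard_length_cm`).
#' @param cfg A [scene_config()]; set `yaw_sd > 0` for field emulation.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A list with `annotations` (fish CSV dialect) and `truth`
#'   (`fish_id`, `true_length_cm`, `distance_m`, `yaw_deg`,
#'   `expected_translation`, `expect_filtered`).
#' @export
generate_fish_scene <- function(population, cfg = scene_config(),
                                seed = cfg$seed) {
  stopifnot(all(c("fish_id", "standard_length_cm") %in% names(population)))
  with_local_seed(seed, {
    rig <- cfg$rig
    f <- vertical_focal_a(rig)
    n <- nrow(population)
    z <- stats::runif(n, cfg$distance_range[1], cfg$distance_range[2])
    yaw <- stats::rnorm(n, 0, cfg$yaw_sd) * pi / 180
    visible_m <- population$standard_length_cm / 100 * cos(yaw)
    x0 <- stats::runif(n, -0.1, 0.1) * z
    y0 <- stats::runif(n, -0.08, 0.08) * z

    pts <- tibble::tibble(
      x = rep(x0, each = 2) + rep(c(-0.5, 0.5), n) * rep(visible_m, each = 2),
      y = rep(y0, each = 2),
      z = rep(z, each = 2)
    )
    proj <- project_landmark_rows(pts, rig, cfg$landmark_jitter_sd)
    base <- tibble::tibble(
      fish_id = rep(population$fish_id, each = 2),
      landmark = rep(c("snout", "caudal"), n),
      confidence = 1
    )
    disp <- f * rig$baseline / z
    list(
      annotations = dplyr::bind_rows(
        dplyr::mutate(base, frame = "a", u = proj$a$u, v = proj$a$v),
        dplyr::mutate(base, frame = "b", u = proj$b$u, v = proj$b$v)
      ) |>
        dplyr::select("fish_id", "frame", "landmark", "u", "v", "confidence"),
      truth = tibble::tibble(
        fish_id = population$fish_id,
        true_length_cm = population$standard_length_cm,
        distance_m = z,
        yaw_deg = yaw * 180 / pi,
        expected_translation = disp,
        expect_filtered = disp < cfg$min_translation
      )
    )
  })
}
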