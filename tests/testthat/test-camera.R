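test_that("pinhole projection matches hand-computed oracles", {
  rig <- default_rig()
  f <- rig$camera_a$focal_px[1]
  cc <- rig$camera_a$principal_point

  # on-axis point lands on the principal point
  p <- project_points(tibble::tibble(x = 0, y = 0, z = 1), rig, "a")
  expect_equal(c(p$u, p$v), cc)

  # lateral offset: u - c_x = f * x / z (f = 3218.68 px from the 54 deg FOV)
  expect_equal(f, 3218.68, tolerance = 1e-5)
  p <- project_points(tibble::tibble(x = 0.1, y = 0, z = 1), rig, "a")
  expect_equal(p$u - cc[1], 321.868, tolerance = 1e-4)

  # vertical disparity between the two cameras is f * B / z
  w <- tibble::tibble(x = 0.03, y = -0.02, z = 1)
  pa <- project_points(w, rig, "a")
  pb <- project_points(w, rig, "b")
  expect_equal(px_disparity(pa$u, pa$v, pb$u, pb$v), 257.494, tolerance = 1e-4)
  expect_equal(pa$u, pb$u)  # purely vertical baseline

  expect_error(project_points(tibble::tibble(x = 0, y = 0, z = -1), rig, "a"),
               "z > 0")
})

test_that("projected disparity equals f*B/z and is translation invariant", {
  rig <- default_rig()
  f <- rig$camera_a$focal_px[2]
  for (z in c(0.5, 0.8, 1.3, 2.1, 3.0)) {
    pts <- tibble::tibble(x = c(0, 0.2, -0.15), y = c(0, -0.1, 0.12), z = z)
    pa <- project_points(pts, rig, "a")
    pb <- project_points(pts, rig, "b")
    d <- px_disparity(pa$u, pa$v, pb$u, pb$v)
    expect_equal(d, rep(f * rig$baseline / z, 3), tolerance = 1e-9)
    # and the analytic scale equals the true metres-per-pixel at that depth
    expect_equal(ideal_scale_from_disparity(d[1], rig), z * 1e6 / f,
                 tolerance = 1e-9)
  }
})

test_that("pixel disparity is the Euclidean norm with a vertical option", {
  expect_equal(px_disparity(5, 9, 5, 9), 0)
  expect_equal(px_disparity(0, 0, 0, 140), 140)
  expect_equal(px_disparity(0, 0, 3, 4), 5)
  expect_equal(px_disparity(10, 0, 13, 4, type = "vertical"), 4)
})

test_that("radial distortion follows the Brown model and round-trips", {
  cam <- default_rig()$camera_a

  # zero coefficients and the principal point are fixed points
  pts <- tibble::tibble(u = c(100, 2000), v = c(50, 1800))
  expect_equal(apply_distortion(pts, cam, radial_distortion(0, 0)), pts)
  pp <- tibble::tibble(u = cam$principal_point[1], v = cam$principal_point[2])
  expect_equal(apply_distortion(pp, cam, radial_distortion(-0.2, 0.05)), pp)

  # hand-evaluated displacement at r = 0.5 normalized, k1 = -0.1
  d <- radial_distortion(k1 = -0.1)
  x_u <- 0.3; y_u <- 0.4  # r = 0.5
  p <- tibble::tibble(u = x_u * cam$focal_px[1] + cam$principal_point[1],
                      v = y_u * cam$focal_px[2] + cam$principal_point[2])
  got <- apply_distortion(p, cam, d)
  fac <- 1 - 0.1 * 0.25
  expect_equal(got$u, x_u * fac * cam$focal_px[1] + cam$principal_point[1])
  expect_equal(got$v, y_u * fac * cam$focal_px[2] + cam$principal_point[2])

  # round trip within 1e-6 px for |k1| <= 0.3, r <= 1
  set.seed(101)
  for (k1 in c(-0.3, -0.1, 0.1, 0.3)) {
    dd <- radial_distortion(k1, 0.02)
    r <- sqrt(runif(25)); th <- runif(25, 0, 2 * pi)
    pts <- tibble::tibble(
      u = r * cos(th) * cam$focal_px[1] + cam$principal_point[1],
      v = r * sin(th) * cam$focal_px[2] + cam$principal_point[2]
    )
    back <- undistort(apply_distortion(pts, cam, dd), cam, dd)
    expect_lt(max(abs(back$u - pts$u), abs(back$v - pts$v)), 1e-6)
  }
})

test_that("analytic parallax scale follows B*1e6/d", {
  expect_equal(ideal_scale_from_disparity(160, baseline = 0.08), 500)
  expect_equal(ideal_scale_from_disparity(257.49, baseline = 0.08),
               310.7, tolerance = 1e-4)
  d <- c(150, 230, 410)
  expect_equal(ideal_scale_from_disparity(2 * d, baseline = 0.08),
               ideal_scale_from_disparity(d, baseline = 0.08) / 2)
  expect_error(ideal_scale_from_disparity(0, baseline = 0.08), "positive")
  expect_error(ideal_scale_from_disparity(-5, baseline = 0.08), "positive")
})

test_that("rig construction validates geometry and serializes to JSON", {
  expect_error(stereo_rig(camera_intrinsics(), baseline = 0), "baseline")
  small <- camera_intrinsics(resolution = c(640, 480), fov = c(54, 41))
  expect_error(stereo_rig(camera_intrinsics(), small), "resolution")

  rig <- default_rig(k1 = -0.05, k2 = 0.01, medium_index = 1.33)
  path <- withr::local_tempfile(fileext = ".json")
  write_rig(rig, path)
  rig2 <- read_rig(path)
  expect_equal(rig2$camera_a$focal_px, rig$camera_a$focal_px)
  expect_equal(rig2$baseline, rig$baseline)
  expect_equal(rig2$distortion$k1, -0.05)
  expect_equal(rig2$medium_index, 1.33)
  expect_identical(rig_hash(rig2), rig_hash(rig))
  expect_false(identical(rig_hash(default_rig()), rig_hash(rig)))

  # medium index scales the effective focal and hence disparity
  pa <- project_points(tibble::tibble(x = 0, y = 0, z = 1), rig, "a")
  pb <- project_points(tibble::tibble(x = 0, y = 0, z = 1), rig, "b")
  expect_equal(px_disparity(pa$u, pa$v, pb$u, pb$v),
               1.33 * 3218.68 * 0.08, tolerance = 1e-3)
})
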