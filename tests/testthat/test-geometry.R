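test_that("polar returns map into the sensor plane as (-s cos, 0, s sin, 1)", {
  expect_equal(as.vector(polar_to_sensor_plane(70, 0)), c(-70, 0, 0, 1))
  expect_equal(as.vector(polar_to_sensor_plane(70, 90)), c(0, 0, 70, 1),
               tolerance = 1e-12)
  expect_equal(as.vector(polar_to_sensor_plane(100, 30)),
               c(-86.6025, 0, 50, 1), tolerance = 1e-4)
  expect_error(polar_to_sensor_plane(0, 0), "valid return")
})

test_that("tilt transform pitches the scan fan within the vertical plane", {
  expect_equal(tilt_transform(0), diag(4))
  # a 90-degree pitch maps +Z' onto +X'
  expect_equal(as.vector(tilt_transform(89.9999) %*% c(0, 0, 1, 1)),
               c(1, 0, 0, 1), tolerance = 1e-5)
  # tilting a beam return is a pure beam-angle offset: s = 100, theta = 30
  # tilted by 10 degrees equals the untilted return at theta = 40
  p <- tilt_transform(10) %*% as.vector(polar_to_sensor_plane(100, 30))
  expect_equal(as.vector(p), as.vector(polar_to_sensor_plane(100, 40)),
               tolerance = 1e-9)
  expect_error(tilt_transform(90), "\\(-90, 90\\)")
})

test_that("sensor-to-disc translation adds d to x and h to z", {
  expect_equal(sensor_to_disc_translation(1e-9, 0), diag(4),
               tolerance = 1e-8)
  # a return at s = d with theta = 0 lands on the disc axis at height h
  expect_equal(as.vector(sensor_to_disc_translation(100, 20) %*%
                           c(-100, 0, 0, 1)), c(0, 0, 20, 1))
  expect_equal(as.vector(sensor_to_disc_translation(70, -5) %*% c(0, 0, 0, 1)),
               c(70, 0, -5, 1))
})

test_that("disc rotation turns points about the vertical axis", {
  expect_equal(disc_rotation(0), diag(4))
  expect_equal(as.vector(disc_rotation(90) %*% c(1, 0, 0, 1)),
               c(0, 1, 0, 1), tolerance = 1e-12)
  expect_equal(as.vector(disc_rotation(30) %*% c(1, 1, 0, 1)),
               c(cos(pi / 6) - sin(pi / 6), sin(pi / 6) + cos(pi / 6), 0, 1),
               tolerance = 1e-12)
})

test_that("all chain transforms are rigid isometries and rotations compose", {
  set.seed(11)
  pts <- cbind(matrix(runif(60, -50, 50), ncol = 3), 1)
  pair_d <- function(m) as.vector(dist(m[, 1:3]))
  for (m in list(tilt_transform(17.3), sensor_to_disc_translation(88, -12),
                 disc_rotation(211.7))) {
    expect_equal(pair_d(t(m %*% t(pts))), pair_d(pts), tolerance = 1e-9)
    expect_equal(t(m %*% t(pts))[, 4], rep(1, nrow(pts)))
  }
  expect_equal(disc_rotation(123.4) %*% disc_rotation(77.7),
               disc_rotation(123.4 + 77.7), tolerance = 1e-9)
})

test_that("profile reconstruction equals the single composed-matrix oracle", {
  calib <- platform_calibration(120, 15, 3.5)
  prof <- profile(c(-10, 0, 12.5), c(118, 121, 119), intensity = c(.2, .5, .9),
                  disc_angle_deg = 45)
  got <- reconstruct_profile(prof, calib)
  m <- disc_rotation(45) %*% sensor_to_disc_translation(calib) %*%
    tilt_transform(3.5)
  p1 <- polar_to_sensor_plane(prof$distance_cm, prof$beam_angle_deg)
  expect_equal(unname(got$points), unname(t(m %*% t(p1))[, 1:3]),
               tolerance = 1e-9)
  expect_equal(got$intensity, c(.2, .5, .9))
})

test_that("on-axis returns are invariant to the disc angle", {
  calib <- platform_calibration(100, 20, 0)
  for (phi in c(0, 90, 217)) {
    p <- profile(0, 100, disc_angle_deg = phi)
    expect_equal(unname(reconstruct_profile(p, calib)$points),
                 matrix(c(0, 0, 20), 1), tolerance = 1e-12)
  }
})

test_that("scan reconstruction concatenates profiles and handles empties", {
  calib <- platform_calibration(100, 0, 0)
  expect_equal(n_points(reconstruct_scan(list(), calib)), 0)
  expect_equal(n_points(reconstruct_profile(
    profile(numeric(0), numeric(0)), calib)), 0)
  # two half scans equal one full scan on the same raw data
  sc <- build_cube(5.5)
  scanner <- quick_scanner(res = 1)
  full <- simulate_scan(sc, scanner, turntable_config(step_deg = 30),
                        calib, noise = FALSE)
  h1 <- simulate_scan(sc, scanner,
                      turntable_config(step_deg = 30, end_deg = 180),
                      calib, noise = FALSE)
  h2 <- simulate_scan(sc, scanner,
                      turntable_config(step_deg = 30, start_deg = 180),
                      calib, noise = FALSE)
  joined <- reconstruct_scan(c(h1$profiles, h2$profiles), calib)
  expect_equal(joined$points, reconstruct_scan(full$profiles, calib)$points)
})

test_that("gear-train arithmetic gives the platform resolution", {
  expect_identical(steps_per_revolution(10000, 36), 360000)
  expect_identical(platform_resolution_deg(360000), 0.001)
})
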