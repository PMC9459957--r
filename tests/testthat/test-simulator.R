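test_that("the range-noise polynomial evaluates and grows with distance", {
  expect_equal(noise_sigma(0), 0.0589)
  expect_equal(noise_sigma(1), 0.0639 + 0.1139 + 0.0473 + 0.0589)
  d <- seq(0.01, 3, by = 0.01)
  expect_true(all(diff(noise_sigma(d)) > 0))
  expect_error(noise_sigma(-1), ">= 0")
  # custom coefficients are honoured
  expect_equal(noise_sigma(2, c(0, 0, 1, 0.5)), 2.5)
})

test_that("the cube scene is a watertight unit-volume-scaling solid", {
  sc <- build_cube(5.5)
  expect_equal(apply(sc$vertices, 2, max) - apply(sc$vertices, 2, min),
               c(x = 5.5, y = 5.5, z = 5.5))
  expect_equal(min(sc$vertices[, 3]), 0)
  expect_equal(abs(mesh_volume(build_cube(1))), 1, tolerance = 1e-12)
  # 12 edges of equal length on the wireframe
  sc1 <- build_cube(2)
  e <- unique(t(apply(cbind(rbind(sc1$faces[, 1:2], sc1$faces[, 2:3],
                                  sc1$faces[, c(1, 3)])), 1, sort)))
  len <- sqrt(rowSums((sc1$vertices[e[, 1], ] - sc1$vertices[e[, 2], ])^2))
  expect_equal(sort(unique(round(len, 9))), c(2, sqrt(8)))
  expect_equal(sum(abs(len - 2) < 1e-9), 12)
})

test_that("the planar target stands vertically with the stated extents", {
  sc <- build_target(include_disc = FALSE)
  expect_equal(diff(range(sc$vertices[, 3])), 40)
  expect_equal(diff(range(sc$vertices[, 2])), 4.5)
  expect_true(all(sc$vertices[, 1] == 0))  # face normal is horizontal
  expect_true("disc" %in% build_target()$labels)
})

test_that("seedling scenes are deterministic and respect their parameters", {
  p <- seedling_params(stem_height_cm = 30, n_leaves = 4, seed = 42)
  s1 <- build_seedling(p)
  s2 <- build_seedling(seedling_params(stem_height_cm = 30, n_leaves = 4,
                                       seed = 42))
  expect_identical(s1$vertices, s2$vertices)
  expect_gte(max(s1$vertices[, 3]), 30)  # leaves may arch above the stem tip
  bare <- build_seedling(seedling_params(stem_height_cm = 20, n_leaves = 0,
                                         seed = 1))
  expect_equal(max(bare$vertices[, 3]), 20, tolerance = 1e-12)
  expect_error(seedling_params(stem_height_cm = 45), "\\[10, 40\\]")
  pot <- build_seedling(seedling_params(stem_height_cm = 15, n_leaves = 2,
                                        pot_height_cm = 8, seed = 3))
  expect_true(all(c("stem", "leaf", "pot") %in% pot$labels))
})

test_that("profile casting hits at the true distance and drops missed beams", {
  calib <- platform_calibration(100, 2, 0)
  empty <- scene(matrix(numeric(0), ncol = 3),
                 matrix(integer(0), ncol = 3), character(0))
  expect_equal(nrow(cast_profile(empty, quick_scanner(), calib, 0)), 0)
  # cube face at exactly 100 cm for the horizontal beam
  sc <- build_cube(5.5)
  calib2 <- platform_calibration(100 + 2.75, 2, 0)
  prof <- cast_profile(sc, quick_scanner(res = 0.0833), calib2, 0,
                       noise = FALSE)
  # nearest beam to horizontal: range is the plane distance over cos(theta)
  i0 <- which.min(abs(prof$beam_angle_deg))
  expect_equal(prof$distance_cm[i0],
               100 / cos(prof$beam_angle_deg[i0] * pi / 180),
               tolerance = 1e-9)
  # a scene beyond the working range yields no returns
  far <- platform_calibration(400, 2, 0)
  expect_equal(nrow(cast_profile(sc, quick_scanner(), far, 0, noise = FALSE)),
               0)
})

test_that("simulated range noise matches the configured sigma", {
  scanner <- scanner_config(repeat_count = 1, rng_seed = 21)
  set.seed(21)
  disp <- dispersion_experiment(scanner, distances_m = 1,
                                repetitions = 4000)
  # normal incidence at 1 m: sample sd within 5% of sigma(1)
  expect_equal(disp$sigma_cm, noise_sigma(1), tolerance = 0.05)
})

test_that("repeat averaging reduces the per-sample dispersion by sqrt(n)", {
  scanner <- scanner_config(repeat_count = 25, rng_seed = 8)
  set.seed(8)
  disp <- dispersion_experiment(scanner, distances_m = 1, repetitions = 300)
  expect_equal(disp$sigma_cm, noise_sigma(1) / 5, tolerance = 0.15)
})

test_that("scans cover the commanded range and are seed-reproducible", {
  calib <- platform_calibration(100, 2, 0)
  sc <- build_cube(5.5)
  s4 <- simulate_scan(sc, quick_scanner(res = 1), turntable_config(90),
                      calib, noise = FALSE)
  expect_length(s4$profiles, 4)
  expect_length(simulate_scan(sc, quick_scanner(res = 1),
                              turntable_config(10), calib,
                              noise = FALSE)$profiles, 36)
  a <- simulate_scan(sc, quick_scanner(res = 1, repeats = 5, seed = 99),
                     turntable_config(45), calib)
  b <- simulate_scan(sc, quick_scanner(res = 1, repeats = 5, seed = 99),
                     turntable_config(45), calib)
  expect_identical(a$profiles, b$profiles)
})

test_that("noiseless scans reconstruct exactly onto the generating surface", {
  calib <- platform_calibration(100, 20, 1.5)
  sc <- build_cube(5.5)
  cl <- sim_cloud(sc, calib, step_deg = 5, quick_scanner(res = 0.25))
  expect_gt(n_points(cl), 1000)
  expect_lt(max(point_to_mesh_distance(cl, sc)), 1e-6)
  # ground truth of a noisy scan is also exact
  scan <- simulate_scan(sc, quick_scanner(res = 0.5, repeats = 3, seed = 1),
                        turntable_config(15), calib, noise = TRUE)
  expect_lt(max(point_to_mesh_distance(scan$ground_truth, sc)), 1e-6)
})

test_that("thin leaves collect fewer returns per unit area than the stem", {
  p <- seedling_params(stem_height_cm = 25, n_leaves = 3, seed = 5)
  sc <- build_seedling(p)
  calib <- platform_calibration(120, 25, 0)
  scan <- simulate_scan(sc, quick_scanner(res = 0.25),
                        turntable_config(step_deg = 5), calib, noise = FALSE)
  gt <- scan$ground_truth
  tri_area <- function(s, lab) {
    f <- s$faces[s$labels == lab, , drop = FALSE]
    a <- s$vertices[f[, 1], , drop = FALSE]
    ab <- s$vertices[f[, 2], , drop = FALSE] - a
    ac <- s$vertices[f[, 3], , drop = FALSE] - a
    cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  dens <- function(lab) sum(gt$label == lab) / tri_area(sc, lab)
  expect_lt(dens("leaf"), dens("stem"))
})
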