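test_that("individual errors are absolute percent deviations", {
  expect_equal(individual_error(5.4383, 5.5), 1.1218, tolerance = 1e-4)
  expect_equal(individual_error(5.3051, 5.5), 3.5436, tolerance = 1e-4)
  expect_equal(individual_error(7, 7), 0)
  # errors are positive for over- and under-estimates alike
  expect_equal(individual_error(5.5573, 5.5), individual_error(5.4427, 5.5),
               tolerance = 1e-12)
  expect_error(individual_error(1, 0), "nonzero")
})

test_that("the absolute error follows the standard-error formula", {
  expect_equal(absolute_error(c(1, 2, 3)), sqrt(2 / 6))
  expect_equal(absolute_error(rep(4, 12)), 0)
  expect_error(absolute_error(1), "at least 2")
})

test_that("the bundled reference edge set reproduces every derived cell", {
  rep <- error_report(reference_cube_edges())
  e <- rep$edges
  expect_equal(e$indiv_error_pct[e$edge_id == "U1"], 1.1218,
               tolerance = 1e-4)
  expect_equal(unname(rep$axis_mean_pct["X"]), 1.6773, tolerance = 1e-4)
  expect_equal(unname(rep$axis_mean_pct["Y"]), 2.1418, tolerance = 1e-4)
  expect_equal(unname(rep$axis_mean_pct["Z"]), 1.6755, tolerance = 1e-4)
  expect_equal(round(rep$accuracy_pct, 4), 1.8315)
  expect_equal(round(rep$mean_m_cm, 4), 5.4517)
  expect_equal(round(rep$sum_sq_dev_cm2, 4), 0.1271)
  expect_equal(round(rep$abs_error_cm, 4), 0.0310)
})

test_that("perfect measurements give an all-zero report", {
  edges <- edge_measurements(c(paste0("U", 1:4), paste0("D", 1:4),
                               paste0("L", 1:4)), 5.5, rep(5.5, 12))
  rep <- error_report(edges)
  expect_equal(rep$accuracy_pct, 0)
  expect_equal(rep$abs_error_cm, 0)
})

test_that("malformed edge sets are rejected", {
  expect_error(edge_measurements("Q9", 5.5, 5.5), "unknown edge")
  good <- reference_cube_edges()
  expect_error(error_report(good[1:11, ]), "exactly the 12")
  dup <- good
  dup$edge_id[2] <- "U1"
  expect_error(error_report(dup), "exactly the 12")
})

test_that("cube edges measure exactly on analytic surface samples", {
  cl <- cube_surface_points(5.5, n = 25)
  edges <- measure_cube_edges(cl, ref_cm = 5.5, inlier_tol_cm = 0.05)
  expect_setequal(edges$edge_id, c(paste0("U", 1:4), paste0("D", 1:4),
                                   paste0("L", 1:4)))
  expect_lt(max(abs(edges$measured_cm - 5.5)), 1e-6)
  # edge ids carry the U/D/L axis convention
  expect_equal(unique(edges$axis[edges$edge_id %in% c("U1", "U2")]), "X")
  expect_equal(unique(edges$axis[edges$edge_id %in% c("U3", "U4")]), "Y")
  expect_equal(unique(edges$axis[grepl("^L", edges$edge_id)]), "Z")
})

test_that("cube metrology survives a rotated cube up to relabeling", {
  cl <- cube_surface_points(5.5, n = 25)
  rot <- disc_rotation(25)[1:3, 1:3]
  cl_rot <- point_cloud(cl$points %*% t(rot))
  e0 <- measure_cube_edges(cl, 5.5, inlier_tol_cm = 0.05)
  e1 <- measure_cube_edges(cl_rot, 5.5, inlier_tol_cm = 0.05)
  expect_equal(sort(e1$measured_cm), sort(e0$measured_cm), tolerance = 1e-6)
})

test_that("simulated cube scans yield edges near the reference", {
  calib <- platform_calibration(100, 20, 0)
  sc <- build_cube(5.5)
  cl <- sim_cloud(sc, calib, step_deg = 3, quick_scanner(res = 0.2))
  edges <- measure_cube_edges(cl, ref_cm = 5.5)
  expect_lt(max(abs(edges$measured_cm - 5.5)), 0.01)
  expect_error(measure_cube_edges(point_cloud(matrix(runif(30), ncol = 3))),
               "not resolvable")
})

test_that("the precision polynomial is recovered from exact pairs", {
  d <- seq(0.7, 3, length.out = 10)
  fit <- fit_precision_polynomial(d, noise_sigma(d))
  expect_equal(fit$coefficients, c(0.0639, 0.1139, 0.0473, 0.0589),
               tolerance = 1e-9)
  expect_equal(predict(fit, d), noise_sigma(d), tolerance = 1e-9)
  # constant dispersions collapse onto the intercept
  flat <- fit_precision_polynomial(d, rep(0.07, 10))
  expect_equal(flat$coefficients, c(0, 0, 0, 0.07), tolerance = 1e-9)
  expect_error(fit_precision_polynomial(c(1, 1, 2, 3), rep(1, 4)),
               "4 distinct")
})

test_that("dispersion vanishes without noise and grows with distance", {
  silent <- scanner_config(repeat_count = 1, noise_coeffs = c(0, 0, 0, 0),
                           rng_seed = 1)
  disp0 <- dispersion_experiment(silent, c(0.8, 1.5), repetitions = 10)
  expect_equal(disp0$sigma_cm, c(0, 0))
  noisy <- scanner_config(repeat_count = 1, rng_seed = 2)
  set.seed(2)
  disp <- dispersion_experiment(noisy, c(0.8, 2.0, 2.9), repetitions = 200)
  expect_true(all(diff(disp$sigma_cm) > 0))
})

test_that("error reports serialize to JSON and table-shaped CSV", {
  rep <- error_report(reference_cube_edges())
  jf <- tempfile(fileext = ".json")
  cf <- tempfile(fileext = ".csv")
  write_error_report(rep, json_path = jf, csv_path = cf)
  j <- jsonlite::read_json(jf)
  expect_equal(j$abs_error_cm, rep$abs_error_cm, tolerance = 1e-12)
  tab <- read.table(cf, header = TRUE, sep = ",", comment.char = "#")
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$dev2), rep$sum_sq_dev_cm2, tolerance = 1e-9)
})
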