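# Software stand-in for the physical platform: ray-casts range profiles of
# parametric scenes under the scanner model (70 deg aperture, 0.0833 deg
# angular resolution, 70-300 cm working range), distance-dependent Gaussian
# range noise with repeat averaging, and turntable stepping.

#' Scanner configuration
#'
#' Parameters of the 2D range scanner: the vertical fan geometry, the working
#' range, the repeat-averaging count and the range-noise model. The noise
#' standard deviation is a cubic polynomial in the distance (see
#' [noise_sigma()]); defaults are the fitted precision curve of the platform.
#'
#' @param aperture_deg full aperture of the vertical fan (degrees).
#' @param angular_resolution_deg beam spacing within the fan (degrees).
#' @param range_min_cm,range_max_cm working range (cm); returns outside it
#'   are missed beams.
#' @param repeat_count acquisitions averaged per profile (>= 1).
#' @param noise_coeffs cubic noise-polynomial coefficients `(a3, a2, a1, a0)`,
#'   distance in meters, sigma in cm.
#' @param rng_seed integer seed controlling all simulated noise, or `NULL`.
#' @return An object of class `scanner_config`.
#' @export
scanner_config <- function(aperture_deg = 70, angular_resolution_deg = 0.0833,
                           range_min_cm = 70, range_max_cm = 300,
                           repeat_count = 100,
                           noise_coeffs = c(0.0639, 0.1139, 0.0473, 0.0589),
                           rng_seed = NULL) {
  stopifnot(aperture_deg > 0, angular_resolution_deg > 0,
            range_min_cm < range_max_cm, repeat_count >= 1,
            length(noise_coeffs) == 4)
  structure(list(aperture_deg = aperture_deg,
                 angular_resolution_deg = angular_resolution_deg,
                 range_min_cm = range_min_cm, range_max_cm = range_max_cm,
                 repeat_count = as.integer(repeat_count),
                 noise_coeffs = as.numeric(noise_coeffs),
                 rng_seed = if (!is.null(rng_seed)) as.integer(rng_seed)),
            class = "scanner_config")
}

#' Turntable configuration
#'
#' @param step_deg angular step between profiles (degrees), default the
#'   platform's selected 0.1 degree resolution.
#' @param start_deg,end_deg commanded scan range; one profile is acquired per
#'   step in `[start_deg, end_deg)`.
#' @return An object of class `turntable_config`.
#' @export
turntable_config <- function(step_deg = 0.1, start_deg = 0, end_deg = 360) {
  stopifnot(step_deg > 0, step_deg <= 360,
            start_deg < end_deg, end_deg <= start_deg + 360)
  structure(list(step_deg = step_deg, start_deg = start_deg,
                 end_deg = end_deg),
            class = "turntable_config")
}

#' Range-noise standard deviation
#'
#' Evaluates the platform's precision curve: a cubic polynomial in the
#' sensor-to-surface distance giving the standard deviation of a single
#' range measurement. The distance is in meters, the result in centimeters.
#'
#' @param distance_m distance(s) in meters, >= 0.
#' @param coeffs polynomial coefficients `(a3, a2, a1, a0)`.
#' @return Standard deviation(s) in cm.
#' @export
noise_sigma <- function(distance_m,
                        coeffs = c(0.0639, 0.1139, 0.0473, 0.0589)) {
  if (any(distance_m < 0)) stop("distance must be >= 0")
  stopifnot(length(coeffs) == 4)
  ((coeffs[1] * distance_m + coeffs[2]) * distance_m + coeffs[3]) *
    distance_m + coeffs[4]
}

beam_angles <- function(scanner) {
  half <- scanner$aperture_deg / 2
  seq(-half, half, by = scanner$angular_resolution_deg)
}

#' Cast one profile of a scene
#'
#' Ray-casts the vertical fan of the scanner against the scene at one
#' turntable angle. The scene is expressed in the disc frame; for a profile at
#' disc angle phi the specimen has physically turned by -phi relative to the
#' fixed sensor, so the scene is rotated by -phi and intersected with rays
#' leaving the (tilted) sensor origin. The nearest intersection per beam gives
#' the true distance; true distances outside the working range are missed
#' beams. The measured distance is the mean over `repeat_count` independent
#' Gaussian range-noise draws (draws outside the working range count as
#' missed; a beam missed in more than half of the repeats is dropped). The
#' noise standard deviation is [noise_sigma()] at the true distance, inflated
#' by 1/cos(incidence) capped at 3 to mimic scattering at grazing incidence.
#' Intensity is a Lambertian cosine times an inverse-square falloff
#' `(70/d)^2`, clipped to `[0, 1]`. The hit triangle's part label is recorded
#' as per-return ground truth.
#'
#' @param sc a [scene()].
#' @param scanner a [scanner_config()].
#' @param calib a [platform_calibration()].
#' @param disc_angle_deg turntable angle of the profile (degrees).
#' @param noise simulate range noise (`FALSE` gives exact true distances).
#' @return A [profile()] with `intensity`, `label` and `true_distance_cm`.
#' @export
cast_profile <- function(sc, scanner, calib, disc_angle_deg = 0,
                         noise = TRUE) {
  stopifnot(inherits(sc, "scene"), inherits(scanner, "scanner_config"),
            inherits(calib, "platform_calibration"))
  th_deg <- beam_angles(scanner)
  th <- deg2rad(th_deg)
  dirs <- cbind(-cos(th), 0, sin(th))
  phi <- disc_angle_deg %% 360

  empty <- profile(numeric(0), numeric(0), intensity = numeric(0),
                   disc_angle_deg = phi, repeat_count = scanner$repeat_count,
                   label = character(0), true_distance_cm = numeric(0))
  if (nrow(sc$faces) == 0) return(empty)

  # scene -> pre-tilt sensor frame
  A <- solve(sensor_pose(calib)) %*% disc_rotation(-phi)
  Vh <- cbind(sc$vertices, 1) %*% t(A)
  V <- Vh[, 1:3, drop = FALSE]

  hit <- cpp_cast_rays(dirs, V, sc$faces - 1L)
  ok <- !is.na(hit$t)
  if (!any(ok)) return(empty)
  s_true <- hit$t[ok]
  tri <- hit$tri[ok]
  in_range <- s_true >= scanner$range_min_cm & s_true <= scanner$range_max_cm
  ok[ok] <- in_range
  if (!any(ok)) return(empty)
  s_true <- s_true[in_range]
  tri <- tri[in_range]
  d_ok <- dirs[ok, , drop = FALSE]

  # incidence angle from the hit triangle's normal (rigid transform, so the
  # sensor-frame normal is valid)
  e1 <- V[sc$faces[tri, 2], , drop = FALSE] - V[sc$faces[tri, 1], , drop = FALSE]
  e2 <- V[sc$faces[tri, 3], , drop = FALSE] - V[sc$faces[tri, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(nrm^2))
  cos_inc <- abs(rowSums(d_ok * nrm)) / pmax(nn, 1e-300)
  cos_inc <- pmin(pmax(cos_inc, 1e-6), 1)

  if (noise) {
    sig <- noise_sigma(s_true / 100, scanner$noise_coeffs) *
      pmin(1 / cos_inc, 3)
    reps <- scanner$repeat_count
    draws <- matrix(rnorm(length(s_true) * reps, mean = s_true, sd = sig),
                    nrow = length(s_true))
    valid <- draws >= scanner$range_min_cm & draws <= scanner$range_max_cm
    n_valid <- rowSums(valid)
    s_meas <- rowSums(draws * valid) / pmax(n_valid, 1)
    keep <- n_valid > reps / 2
  } else {
    s_meas <- s_true
    keep <- rep(TRUE, length(s_true))
  }
  if (!any(keep)) return(empty)

  intens <- pmin(pmax(cos_inc * (70 / s_true)^2, 0), 1)
  profile(beam_angle_deg = th_deg[ok][keep],
          distance_cm = s_meas[keep],
          intensity = intens[keep],
          disc_angle_deg = phi,
          repeat_count = scanner$repeat_count,
          label = sc$labels[tri][keep],
          true_distance_cm = s_true[keep])
}

#' Simulate a full turntable scan
#'
#' Acquires one profile per turntable step over the commanded range and
#' assembles the ground truth: the noiseless reconstruction of the same valid
#' returns, index-aligned with the raw profiles and carrying the true part
#' labels.
#'
#' @inheritParams cast_profile
#' @param turntable a [turntable_config()].
#' @return A list of class `lidar_scan` with elements `profiles` (list of
#'   [profile()]) and `ground_truth` (labeled [point_cloud()]).
#' @export
simulate_scan <- function(sc, scanner, turntable, calib, noise = TRUE) {
  stopifnot(inherits(turntable, "turntable_config"))
  n_steps <- floor((turntable$end_deg - turntable$start_deg) /
                     turntable$step_deg + 1e-9)
  angles <- (turntable$start_deg + turntable$step_deg * (seq_len(n_steps) - 1)) %% 360
  if (!is.null(scanner$rng_seed)) set.seed(scanner$rng_seed)
  profiles <- lapply(angles, function(a)
    cast_profile(sc, scanner, calib, disc_angle_deg = a, noise = noise))
  gt <- reconstruct_scan(profiles, calib, use_true_distance = TRUE)
  structure(list(profiles = profiles, ground_truth = gt),
            class = "lidar_scan")
}

#' Distance from points to the nearest scene surface
#'
#' Geometric oracle used to verify that reconstructed scans lie on the
#' generating surface.
#'
#' @param cloud a [point_cloud()] in the disc frame.
#' @param sc the generating [scene()].
#' @return Numeric vector of unsigned point-to-mesh distances (cm).
#' @export
point_to_mesh_distance <- function(cloud, sc) {
  if (n_points(cloud) == 0) return(numeric(0))
  cpp_point_mesh_distance(cloud$points, sc$vertices, sc$faces - 1L)
}
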