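#' Construct a polar range profile
#'
#' A profile is one vertical sweep of the 2D scanner at a fixed turntable
#' (disc) angle. Only valid returns are stored, one row per return, ordered by
#' strictly increasing beam angle; beams with no return are simply absent.
#'
#' @param beam_angle_deg numeric vector of beam angles theta (degrees,
#'   positive upward, 0 horizontal).
#' @param distance_cm numeric vector of measured distances s (cm), all > 0.
#' @param intensity optional numeric vector of return intensities (>= 0).
#' @param disc_angle_deg turntable angle phi of the sweep, in `[0, 360)`.
#' @param repeat_count number of acquisitions averaged per beam.
#' @param label optional character vector of ground-truth labels per return
#'   (simulator output).
#' @param true_distance_cm optional noiseless distances (simulator output).
#' @return An object of class `lidar_profile`: a data frame with columns
#'   `beam_angle_deg`, `distance_cm` and optionally `intensity`, `label`,
#'   `true_distance_cm`, with attributes `disc_angle_deg` and `repeat_count`.
#' @export
profile <- function(beam_angle_deg, distance_cm, intensity = NULL,
                    disc_angle_deg = 0, repeat_count = 1L,
                    label = NULL, true_distance_cm = NULL) {
  n <- length(beam_angle_deg)
  stopifnot(length(distance_cm) == n)
  if (n > 0) {
    if (any(distance_cm <= 0)) stop("distances of valid returns must be > 0")
    if (n > 1 && any(diff(beam_angle_deg) <= 0))
      stop("beam angles must be strictly increasing")
  }
  if (disc_angle_deg < 0 || disc_angle_deg >= 360)
    stop("disc_angle_deg must lie in [0, 360)")
  df <- data.frame(beam_angle_deg = as.numeric(beam_angle_deg),
                   distance_cm = as.numeric(distance_cm))
  if (!is.null(intensity)) {
    stopifnot(length(intensity) == n)
    df$intensity <- as.numeric(intensity)
  }
  if (!is.null(label)) {
    stopifnot(length(label) == n)
    df$label <- as.character(label)
  }
  if (!is.null(true_distance_cm)) {
    stopifnot(length(true_distance_cm) == n)
    df$true_distance_cm <- as.numeric(true_distance_cm)
  }
  attr(df, "disc_angle_deg") <- as.numeric(disc_angle_deg)
  attr(df, "repeat_count") <- as.integer(repeat_count)
  class(df) <- c("lidar_profile", "data.frame")
  df
}

#' Platform calibration parameters
#'
#' Geometry linking the sensor to the rotating disc: horizontal distance `d`
#' from the sensor origin to the disc centre O, signed vertical offset `h` of
#' the sensor origin above the disc surface, and the sensor tilt `phi`
#' (pitch of the scan fan within the vertical scan plane). The disc surface
#' defines z = 0 in the reconstruction frame.
#'
#' @param d_cm horizontal sensor-to-disc-centre distance (cm), > 0.
#' @param h_cm signed vertical sensor offset above the disc plane (cm).
#' @param tilt_deg sensor tilt (degrees), in (-90, 90); positive pitches the
#'   scan fan upward.
#' @param target_fit_rms_cm optional RMS residual of the calibration line fit.
#' @return An object of class `platform_calibration`.
#' @export
platform_calibration <- function(d_cm, h_cm = 0, tilt_deg = 0,
                                 target_fit_rms_cm = NA_real_) {
  if (d_cm <= 0) stop("d_cm must be > 0")
  if (tilt_deg <= -90 || tilt_deg >= 90) stop("tilt_deg must lie in (-90, 90)")
  structure(list(d_cm = as.numeric(d_cm), h_cm = as.numeric(h_cm),
                 tilt_deg = as.numeric(tilt_deg),
                 target_fit_rms_cm = as.numeric(target_fit_rms_cm)),
            class = "platform_calibration")
}

#' @export
print.platform_calibration <- function(x, ...) {
  cat(sprintf("platform calibration: d = %.4f cm, h = %.4f cm, tilt = %.4f deg",
              x$d_cm, x$h_cm, x$tilt_deg))
  if (is.finite(x$target_fit_rms_cm))
    cat(sprintf(" (target fit RMS %.4g cm)", x$target_fit_rms_cm))
  cat("\n")
  invisible(x)
}

#' Construct a point cloud
#'
#' @param points numeric matrix (or data frame) with columns x, y, z in cm.
#' @param intensity optional per-point intensity (dimensionless, >= 0).
#' @param label optional per-point category, one of `"stem"`, `"leaf"`,
#'   `"pot"`, `"other"` (or any scene part name).
#' @param frame coordinate frame identifier, `"disc"` or `"sensor_plane"`.
#' @return An object of class `point_cloud`: a list with elements `points`
#'   (n x 3 matrix), optional `intensity` and `label`, and `frame`.
#' @export
point_cloud <- function(points, intensity = NULL, label = NULL,
                        frame = c("disc", "sensor_plane")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), ncol = 3)
  if (ncol(points) != 3) stop("points must have 3 columns (x, y, z)")
  colnames(points) <- c("x", "y", "z")
  n <- nrow(points)
  if (!is.null(intensity) && length(intensity) != n)
    stop("intensity must have one entry per point")
  if (!is.null(label) && length(label) != n)
    stop("label must have one entry per point")
  structure(list(points = points,
                 intensity = if (!is.null(intensity)) as.numeric(intensity),
                 label = if (!is.null(label)) as.character(label),
                 frame = frame),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point cloud: %d points (%s frame)%s%s\n", nrow(x$points),
              x$frame,
              if (!is.null(x$intensity)) ", intensity" else "",
              if (!is.null(x$label)) ", labels" else ""))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

subset_cloud <- function(cloud, keep) {
  point_cloud(cloud$points[keep, , drop = FALSE],
              intensity = if (!is.null(cloud$intensity)) cloud$intensity[keep],
              label = if (!is.null(cloud$label)) cloud$label[keep],
              frame = cloud$frame)
}

bind_clouds <- function(clouds) {
  clouds <- Filter(function(cl) n_points(cl) > 0, clouds)
  if (length(clouds) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  frames <- unique(vapply(clouds, `[[`, "", "frame"))
  if (length(frames) != 1)
    stop("cannot combine point clouds in different frames: ",
         paste(frames, collapse = ", "))
  has_int <- all(vapply(clouds, function(cl) !is.null(cl$intensity), TRUE))
  has_lab <- all(vapply(clouds, function(cl) !is.null(cl$label), TRUE))
  point_cloud(do.call(rbind, lapply(clouds, `[[`, "points")),
              intensity = if (has_int) unlist(lapply(clouds, `[[`, "intensity")),
              label = if (has_lab) unlist(lapply(clouds, `[[`, "label")),
              frame = frames)
}

# ---- homogeneous transform chain -------------------------------------------

#' Polar return to sensor-plane homogeneous coordinates
#'
#' Maps a measured distance s and beam angle theta into the sensor's vertical
#' scan plane X'Z': the point (-s cos(theta), 0, s sin(theta), 1).
#'
#' @param distance_cm measured distances s (cm), > 0.
#' @param beam_angle_deg beam angles theta (degrees).
#' @return An n x 4 matrix of homogeneous points (w = 1).
#' @export
polar_to_sensor_plane <- function(distance_cm, beam_angle_deg) {
  if (any(distance_cm <= 0)) stop("distance must be > 0 for a valid return")
  th <- deg2rad(beam_angle_deg)
  cbind(x = -distance_cm * cos(th), y = 0, z = distance_cm * sin(th), w = 1)
}

#' Sensor tilt transform
#'
#' Rigid rotation about the Y' axis by the sensor tilt: the scan fan is
#' pitched within the vertical X'Z' scan plane, so a tilt acts as an offset
#' on the beam elevation. Positive tilt pitches the fan upward.
#'
#' @param tilt_deg tilt angle in (-90, 90) degrees.
#' @return A 4 x 4 homogeneous transform matrix.
#' @export
tilt_transform <- function(tilt_deg) {
  if (tilt_deg <= -90 || tilt_deg >= 90) stop("tilt must lie in (-90, 90) deg")
  a <- deg2rad(tilt_deg)
  matrix(c(cos(a), 0, sin(a), 0,
           0,      1, 0,      0,
           -sin(a), 0, cos(a), 0,
           0,      0, 0,      1), 4, 4, byrow = TRUE)
}

#' Sensor-to-disc translation
#'
#' Translation aligning the (tilt-corrected) sensor frame with the disc frame:
#' adds d to x and h to z, so the disc centre O becomes the origin and the
#' disc surface the plane z = 0.
#'
#' @param calib a [platform_calibration()], or a numeric d (cm) with `h_cm`.
#' @param h_cm vertical offset when `calib` is numeric.
#' @return A 4 x 4 homogeneous transform matrix.
#' @export
sensor_to_disc_translation <- function(calib, h_cm = 0) {
  if (inherits(calib, "platform_calibration")) {
    d <- calib$d_cm; h <- calib$h_cm
  } else {
    d <- calib; h <- h_cm
  }
  m <- diag(4)
  m[1, 4] <- d
  m[3, 4] <- h
  m
}

#' Disc rotation transform
#'
#' Rotation about the vertical disc axis Z by the turntable angle phi.
#'
#' @param disc_angle_deg turntable angle (degrees, any value; periodic in 360).
#' @return A 4 x 4 homogeneous transform matrix.
#' @export
disc_rotation <- function(disc_angle_deg) {
  a <- deg2rad(disc_angle_deg)
  matrix(c(cos(a), -sin(a), 0, 0,
           sin(a),  cos(a), 0, 0,
           0,       0,      1, 0,
           0,       0,      0, 1), 4, 4, byrow = TRUE)
}

# Pose of the (pre-tilt) sensor frame in the static (phi = 0) disc frame.
sensor_pose <- function(calib) {
  sensor_to_disc_translation(calib) %*% tilt_transform(calib$tilt_deg)
}

apply_transform <- function(m, pts) {
  # pts: n x 4 homogeneous
  t(m %*% t(pts))
}

#' Reconstruct one profile into the disc frame
#'
#' Applies the full homogeneous chain — sensor plane, sensor tilt,
#' sensor-to-disc translation, disc rotation — to every valid return of the
#' profile. Missed beams are absent from the profile and therefore produce no
#' point; intensity and labels are carried through unchanged.
#'
#' @param prof a [profile()].
#' @param calib a [platform_calibration()].
#' @param use_true_distance use the simulator's noiseless distances when
#'   present (ground-truth reconstruction).
#' @return A [point_cloud()] in the disc frame.
#' @export
reconstruct_profile <- function(prof, calib, use_true_distance = FALSE) {
  stopifnot(inherits(prof, "lidar_profile"),
            inherits(calib, "platform_calibration"))
  if (nrow(prof) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  s <- if (use_true_distance && !is.null(prof$true_distance_cm))
    prof$true_distance_cm else prof$distance_cm
  p1 <- polar_to_sensor_plane(s, prof$beam_angle_deg)
  m <- disc_rotation(attr(prof, "disc_angle_deg")) %*% sensor_pose(calib)
  xyz <- apply_transform(m, p1)[, 1:3, drop = FALSE]
  point_cloud(xyz, intensity = prof$intensity, label = prof$label,
              frame = "disc")
}

#' Reconstruct a full scan
#'
#' Concatenates the per-profile reconstructions of a sequence of profiles,
#' giving the 360-degree point cloud of the specimen in the disc frame.
#'
#' @param profiles list of [profile()] objects.
#' @inheritParams reconstruct_profile
#' @return A [point_cloud()] in the disc frame; point count equals the total
#'   number of valid returns.
#' @export
reconstruct_scan <- function(profiles, calib, use_true_distance = FALSE) {
  if (length(profiles) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  bind_clouds(lapply(profiles, reconstruct_profile, calib = calib,
                     use_true_distance = use_true_distance))
}

# ---- gear train -------------------------------------------------------------

#' Turntable gear-train arithmetic
#'
#' The disc is driven by a stepper motor through a worm-and-wheel reduction;
#' the effective steps per disc revolution are the motor steps per revolution
#' multiplied by the worm ratio, and the angular resolution is 360 degrees
#' divided by that count.
#'
#' @param motor_steps_per_rev motor steps per motor revolution.
#' @param worm_ratio worm-and-wheel reduction ratio.
#' @return `steps_per_revolution()`: effective steps per disc revolution.
#' @export
steps_per_revolution <- function(motor_steps_per_rev, worm_ratio) {
  stopifnot(motor_steps_per_rev > 0, worm_ratio > 0)
  motor_steps_per_rev * worm_ratio
}

#' @rdname steps_per_revolution
#' @param steps_per_rev effective steps per disc revolution.
#' @return `platform_resolution_deg()`: disc angular resolution in degrees.
#' @export
platform_resolution_deg <- function(steps_per_rev) {
  stopifnot(steps_per_rev > 0)
  360 / steps_per_rev
}
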