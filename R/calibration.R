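# Platform calibration from a scan of the vertical planar target.
#
# The target stands on the disc, through the disc centre O, facing the sensor.
# In the sensor-plane (X'Z') coordinates of a single sweep the target face is
# a straight line; the turntable surface, when visible below the target,
# contributes a second (near-horizontal) line. The tilt is the signed angle
# between the target line and the Z' axis; after de-tilting, the target line
# is vertical at x = -d, and the target base (intersection with the disc
# line) sits at z = -h.

# total-least-squares line fit: returns unit direction, centroid and RMS
# orthogonal residual
tls_line <- function(xz) {
  ctr <- colMeans(xz)
  d <- sweep(xz, 2, ctr)
  sv <- svd(d, nu = 0, nv = 2)
  v <- sv$v[, 1]
  res <- d %*% sv$v[, 2]
  list(dir = v, centroid = ctr, rms = sqrt(mean(res^2)))
}

line_residuals <- function(xz, fit) {
  d <- sweep(xz, 2, fit$centroid)
  abs(d[, 1] * -fit$dir[2] + d[, 2] * fit$dir[1])
}

# deterministic RANSAC line fit on 2D points
ransac_line <- function(xz, thr, iterations = 250) {
  n <- nrow(xz)
  if (n < 2) return(NULL)
  best <- NULL
  best_n <- 1
  idx <- seq_len(n)
  for (it in seq_len(iterations)) {
    pick <- sample(idx, 2)
    p <- xz[pick[1], ]; q <- xz[pick[2], ]
    v <- q - p
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    v <- v / nv
    r <- abs((xz[, 1] - p[1]) * -v[2] + (xz[, 2] - p[2]) * v[1])
    inl <- r <= thr
    if (sum(inl) > best_n) {
      best_n <- sum(inl)
      best <- inl
    }
  }
  if (is.null(best)) return(NULL)
  refine_line(xz, best, thr)
}

# iteratively trimmed TLS: re-fit and shrink the inlier band toward 3x the
# fit RMS, which peels off points of a neighbouring structure (e.g. the other
# line near the target-base corner) and converges to the exact line on
# noiseless data
refine_line <- function(xz, inliers, thr) {
  fit <- tls_line(xz[inliers, , drop = FALSE])
  for (it in 1:20) {
    band <- min(thr, max(3 * fit$rms, 1e-9))
    new_inl <- line_residuals(xz, fit) <= band
    if (sum(new_inl) < 2 || identical(new_inl, inliers)) break
    inliers <- new_inl
    fit <- tls_line(xz[inliers, , drop = FALSE])
  }
  fit$inliers <- inliers
  fit
}

#' Calibrate the platform from a planar-target scan
#'
#' Estimates the platform geometry (d, h, tilt) from one or a few profiles of
#' the vertical planar calibration target standing through the disc centre.
#' The sensor-plane points of the sweep are split into a dominant
#' near-vertical line (the target face) and, when the turntable surface is in
#' view, a second near-horizontal line (the disc). The tilt is the signed
#' angle between the target line and the Z' axis; after de-tilting, d is the
#' horizontal distance to the target line and h places the target base — the
#' intersection of the two lines, or the lowest target return when no disc
#' line is visible — on the disc surface z = 0.
#'
#' @param target_profiles a [profile()] or list of profiles of the target.
#' @param inlier_tol_cm RANSAC inlier tolerance for the line split (cm).
#' @param max_rms_cm maximum acceptable RMS residual of the target line fit;
#'   above it the target is rejected as not planar/vertical.
#' @param seed integer seed for the (deterministic) robust fit.
#' @return A [platform_calibration()] with `target_fit_rms_cm` set.
#' @export
calibrate_from_target <- function(target_profiles, inlier_tol_cm = 0.5,
                                  max_rms_cm = 0.5, seed = 1L) {
  if (inherits(target_profiles, "lidar_profile"))
    target_profiles <- list(target_profiles)
  xz <- do.call(rbind, lapply(target_profiles, function(p) {
    if (nrow(p) == 0) return(NULL)
    h <- polar_to_sensor_plane(p$distance_cm, p$beam_angle_deg)
    h[, c(1, 3), drop = FALSE]
  }))
  if (is.null(xz) || nrow(xz) < 2) stop("insufficient target returns")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  fit1 <- ransac_line(xz, thr = inlier_tol_cm)
  if (is.null(fit1)) stop("insufficient target returns")
  rest <- xz[!fit1$inliers, , drop = FALSE]
  fit2 <- if (nrow(rest) >= 5) ransac_line(rest, thr = inlier_tol_cm)

  # the target line is the more vertical of the two
  is_vertical <- function(f) abs(f$dir[2]) >= abs(f$dir[1])
  target_fit <- fit1; target_xz <- xz
  if (!is.null(fit2) && !is_vertical(fit1) && is_vertical(fit2)) {
    target_fit <- fit2; target_xz <- rest
  }
  if (!is_vertical(target_fit))
    stop("target not planar/vertical: no near-vertical line found")
  if (target_fit$rms > max_rms_cm)
    stop(sprintf("target not planar/vertical: line fit RMS %.3f cm > %.3f cm",
                 target_fit$rms, max_rms_cm))

  # signed angle between the fitted line and the Z' axis; the sensor-plane
  # image of the target is the physical line rotated by -tilt about Y'
  v <- target_fit$dir
  if (v[2] < 0) v <- -v
  tilt_deg <- -rad2deg(atan2(v[1], v[2]))

  detilt <- tilt_transform(tilt_deg)[c(1, 3), c(1, 3)]
  target_pts <- target_xz[target_fit$inliers, , drop = FALSE] %*% t(detilt)
  d_cm <- -mean(target_pts[, 1])
  if (d_cm <= 0) stop("target appears behind the sensor; check the scan")

  # Height: any return from the turntable surface de-tilts to exactly
  # z = -h, because the disc is the z = 0 reference plane. Disc candidates
  # are the non-target returns lying in front of the target face and no
  # higher than its lowest return.
  all_detilt <- xz %*% t(detilt)
  win <- abs(all_detilt[, 1] + d_cm) <= 25
  base_z <- min(all_detilt[win, 2])
  h_cm <- -base_z

  platform_calibration(d_cm = d_cm, h_cm = h_cm, tilt_deg = tilt_deg,
                       target_fit_rms_cm = target_fit$rms)
}
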