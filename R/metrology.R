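# Accuracy/precision metrology: cube-edge measurement, individual and
# absolute errors, and the cubic precision-polynomial fit.

EDGE_AXIS <- c(U1 = "X", U2 = "X", D1 = "X", D2 = "X",
               U3 = "Y", U4 = "Y", D3 = "Y", D4 = "Y",
               L1 = "Z", L2 = "Z", L3 = "Z", L4 = "Z")

#' Construct a set of cube-edge measurements
#'
#' Named measurements of the reference cube's edges: `U1..U4` on the top
#' face, `D1..D4` on the bottom face (these are horizontal, assigned to the X
#' or Y axis), and the vertical front edges `L1..L4` (Z axis).
#'
#' @param edge_id character vector of edge identifiers (`U1..U4`, `D1..D4`,
#'   `L1..L4`).
#' @param ref_cm reference (true) edge length(s), cm.
#' @param measured_cm measured edge length(s), cm.
#' @return A data frame of class `edge_measurements` with columns `edge_id`,
#'   `axis`, `ref_cm`, `measured_cm`.
#' @export
edge_measurements <- function(edge_id, ref_cm, measured_cm) {
  edge_id <- as.character(edge_id)
  if (!all(edge_id %in% names(EDGE_AXIS)))
    stop("unknown edge id(s): ",
         paste(setdiff(edge_id, names(EDGE_AXIS)), collapse = ", "))
  if (any(ref_cm <= 0)) stop("ref_cm must be > 0")
  df <- data.frame(edge_id = edge_id, axis = unname(EDGE_AXIS[edge_id]),
                   ref_cm = as.numeric(ref_cm),
                   measured_cm = as.numeric(measured_cm))
  class(df) <- c("edge_measurements", "data.frame")
  df
}

#' Individual percentage measurement error
#'
#' Absolute relative deviation of a measured length from its reference,
#' in percent: `|m - Ref| / Ref * 100`.
#'
#' @param measured measured value(s).
#' @param ref reference value(s), > 0.
#' @return Percentage error(s), >= 0.
#' @export
individual_error <- function(measured, ref) {
  if (any(ref == 0)) stop("ref must be nonzero")
  abs(measured - ref) / ref * 100
}

#' Absolute (standard) error of a set of measurements
#'
#' The standard error of the mean of N repeated measurements:
#' `sqrt(sum((m - mean(m))^2) / (N * (N - 1)))`.
#'
#' @param m numeric vector of measurements (length >= 2).
#' @return Absolute error, in the units of `m`.
#' @export
absolute_error <- function(m) {
  n <- length(m)
  if (n < 2) stop("need at least 2 measurements")
  sqrt(sum((m - mean(m))^2) / (n * (n - 1)))
}

#' Cube-edge error report
#'
#' Summarises the 12 cube-edge measurements: individual percentage errors,
#' per-axis mean errors (4 edges per axis), overall accuracy (the unweighted
#' mean of the three axis means), the grand mean of the measured lengths, the
#' sum of squared deviations about it, and the absolute error with N = 12.
#'
#' @param edges an [edge_measurements()] data frame with exactly the 12 edges
#'   `U1..U4`, `D1..D4`, `L1..L4`, one each.
#' @return A list of class `error_report` with elements `edges` (per-edge
#'   table including `indiv_error_pct`), `axis_mean_pct` (named X/Y/Z),
#'   `accuracy_pct`, `mean_m_cm`, `sum_sq_dev_cm2`, `abs_error_cm`, `n`.
#' @export
error_report <- function(edges) {
  if (!inherits(edges, "edge_measurements"))
    edges <- edge_measurements(edges$edge_id, edges$ref_cm, edges$measured_cm)
  if (nrow(edges) != 12 || anyDuplicated(edges$edge_id) ||
      !setequal(edges$edge_id, names(EDGE_AXIS)))
    stop("expected exactly the 12 edges U1..U4, D1..D4, L1..L4, one each")
  edges <- edges[match(names(EDGE_AXIS), edges$edge_id), ]
  edges$indiv_error_pct <- individual_error(edges$measured_cm, edges$ref_cm)
  axis_mean <- vapply(c(X = "X", Y = "Y", Z = "Z"), function(a)
    mean(edges$indiv_error_pct[edges$axis == a]), 0)
  m <- edges$measured_cm
  mbar <- mean(m)
  ssq <- sum((m - mbar)^2)
  structure(list(edges = edges,
                 axis_mean_pct = axis_mean,
                 accuracy_pct = mean(axis_mean),
                 mean_m_cm = mbar,
                 sum_sq_dev_cm2 = ssq,
                 abs_error_cm = absolute_error(m),
                 n = length(m)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, digits = 4, ...) {
  e <- x$edges
  cat("Cube-edge measurement error report\n")
  cat(sprintf("%-5s %-4s %8s %9s %12s %10s\n",
              "Coord", "ID", "Ref[cm]", "m[cm]", "Indiv.Err[%]", "AxisMean[%]"))
  for (i in seq_len(nrow(e))) {
    am <- if (i %% 4 == 1) sprintf("%10.4f", x$axis_mean_pct[e$axis[i]]) else ""
    cat(sprintf("%-5s %-4s %8.4f %9.4f %12.4f %s\n",
                e$axis[i], e$edge_id[i], e$ref_cm[i], e$measured_cm[i],
                e$indiv_error_pct[i], am))
  }
  cat(sprintf("Accuracy [%%]     %.4f\n", x$accuracy_pct))
  cat(sprintf("mean m [cm]      %.4f    sum sq dev [cm2]  %.4f\n",
              x$mean_m_cm, x$sum_sq_dev_cm2))
  cat(sprintf("Abs. Error [cm]  %.4f\n", x$abs_error_cm))
  invisible(x)
}

#' Bundled reference cube-edge measurements
#'
#' The measurement set of the platform's 5.5 cm calibration cube (12 edges),
#' bundled for demonstrating and validating the error-report arithmetic.
#'
#' @return An [edge_measurements()] data frame (12 rows).
#' @export
reference_cube_edges <- function() {
  path <- system.file("extdata", "cube_edges_5p5.csv", package = "phenoscan")
  read_edge_csv(path)
}

#' Read / write an edge-measurement CSV
#'
#' Comma-separated file with header `edge_id,axis,ref_cm,measured_cm`
#' (`axis` optional, derived from the id) and `#` comment lines.
#'
#' @param path file path.
#' @return [edge_measurements()] data frame.
#' @export
read_edge_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("edge_id", "ref_cm", "measured_cm") %in% names(df)))
    stop("edge CSV needs columns edge_id, ref_cm, measured_cm")
  edge_measurements(df$edge_id, df$ref_cm, df$measured_cm)
}

#' @rdname read_edge_csv
#' @param edges an [edge_measurements()] data frame.
#' @export
write_edge_csv <- function(edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# phenoscan edge measurements v1; units cm", con)
  write.table(edges, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an error report as JSON and a tabular CSV
#'
#' @param report an [error_report()].
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_error_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "error_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      edges = report$edges,
      axis_mean_pct = as.list(report$axis_mean_pct),
      accuracy_pct = report$accuracy_pct,
      mean_m_cm = report$mean_m_cm,
      sum_sq_dev_cm2 = report$sum_sq_dev_cm2,
      abs_error_cm = report$abs_error_cm,
      n = report$n), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    e <- report$edges
    out <- data.frame(Coord = e$axis, ID = e$edge_id, Ref = e$ref_cm,
                      m = e$measured_cm, IndivError = e$indiv_error_pct,
                      AxisMean = unname(report$axis_mean_pct[e$axis]),
                      dev = e$measured_cm - report$mean_m_cm,
                      dev2 = (e$measured_cm - report$mean_m_cm)^2)
    con <- file(csv_path, "w")
    on.exit(close(con), add = TRUE)
    writeLines("# phenoscan error report v1; lengths cm, errors percent", con)
    write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}

# ---- cube edge measurement from a scan -------------------------------------

# robust plane fit: deterministic RANSAC + TLS refinement
ransac_plane <- function(pts, thr, iterations = 400) {
  n <- nrow(pts)
  if (n < 3) return(NULL)
  best <- NULL; best_n <- 2
  for (it in seq_len(iterations)) {
    pick <- sample.int(n, 3)
    a <- pts[pick[1], ]; b <- pts[pick[2], ]; c2 <- pts[pick[3], ]
    nv <- c((b[2]-a[2])*(c2[3]-a[3]) - (b[3]-a[3])*(c2[2]-a[2]),
            (b[3]-a[3])*(c2[1]-a[1]) - (b[1]-a[1])*(c2[3]-a[3]),
            (b[1]-a[1])*(c2[2]-a[2]) - (b[2]-a[2])*(c2[1]-a[1]))
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-12) next
    nv <- nv / nn
    r <- abs((pts[, 1]-a[1])*nv[1] + (pts[, 2]-a[2])*nv[2] +
               (pts[, 3]-a[3])*nv[3])
    inl <- r <= thr
    if (sum(inl) > best_n) { best_n <- sum(inl); best <- inl }
  }
  if (is.null(best)) return(NULL)
  refine <- function(inl) {
    sub <- pts[inl, , drop = FALSE]
    ctr <- colMeans(sub)
    ev <- eigen(crossprod(sweep(sub, 2, ctr)), symmetric = TRUE)
    nv <- ev$vectors[, 3]
    r <- abs(sweep(pts, 2, ctr) %*% nv)
    list(normal = nv, offset = sum(nv * ctr), resid = r,
         rms = sqrt(mean(r[inl]^2)))
  }
  fit <- refine(best)
  inl <- as.vector(fit$resid) <= max(min(thr, 5 * fit$rms), 1e-9)
  if (sum(inl) >= 3) fit <- refine(inl)
  fit$inliers <- inl
  fit
}

#' Measure the 12 cube edges from a scanned point cloud
#'
#' Segments the visible faces of the scanned cube by sequential robust plane
#' fitting (RANSAC with total-least-squares refinement): the top face and the
#' four side faces. Each cube corner is the intersection of its three
#' adjacent face planes, taking the disc surface z = 0 as the (unscannable)
#' bottom face since the cube rests on the disc. Edge lengths are distances
#' between adjacent corners; horizontal edges are assigned to the X or Y axis
#' by orientation (`U*` on the top face, `D*` on the bottom) and the vertical
#' edges are `L1..L4`.
#'
#' @param cloud a [point_cloud()] of a cube scan in the disc frame.
#' @param ref_cm reference edge length (cm).
#' @param inlier_tol_cm plane-inlier threshold (cm); match about 3x the
#'   per-point noise of the scan (after repeat averaging).
#' @param seed integer seed for the deterministic robust fits.
#' @return An [edge_measurements()] data frame (12 rows).
#' @export
measure_cube_edges <- function(cloud, ref_cm = 5.5, inlier_tol_cm = 0.1,
                               seed = 1L) {
  pts <- cloud$points
  if (nrow(pts) < 100) stop("cube not resolvable: too few points")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (nrow(pts) > 30000) pts <- pts[sample.int(nrow(pts), 30000), ]

  remaining <- pts
  planes <- list()
  min_inl <- max(50, round(0.02 * nrow(pts)))
  for (i in 1:6) {
    if (nrow(remaining) < min_inl) break
    fit <- ransac_plane(remaining, thr = inlier_tol_cm)
    if (is.null(fit) || sum(fit$inliers) < min_inl) break
    fit$points <- remaining[fit$inliers, , drop = FALSE]
    planes[[length(planes) + 1]] <- fit
    remaining <- remaining[!fit$inliers, , drop = FALSE]
  }
  if (length(planes) < 3) stop("cube not resolvable: fewer than 3 planes")

  nz <- vapply(planes, function(p) abs(p$normal[3]), 0)
  top_idx <- which(nz > 0.9)
  side_idx <- which(nz < 0.3)
  if (length(top_idx) < 1 || length(side_idx) < 4)
    stop("cube not resolvable: missing top or side faces")
  if (length(top_idx) > 1)
    top_idx <- top_idx[which.max(vapply(top_idx, function(i)
      mean(planes[[i]]$points[, 3]), 0))]
  if (length(side_idx) > 4)
    side_idx <- side_idx[order(vapply(side_idx, function(i)
      nrow(planes[[i]]$points), 0), decreasing = TRUE)[1:4]]
  top <- planes[[top_idx]]
  sides <- planes[side_idx]
  # outward side normals, ordered by azimuth
  sides <- lapply(sides, function(p) {
    ctr <- colMeans(p$points)
    if (sum(p$normal[1:2] * ctr[1:2]) < 0) {
      p$normal <- -p$normal; p$offset <- -p$offset
    }
    p
  })
  az <- vapply(sides, function(p) atan2(p$normal[2], p$normal[1]), 0)
  sides <- sides[order(az)]

  isect <- function(n1, o1, n2, o2, n3, o3) {
    A <- rbind(n1, n2, n3)
    if (abs(det(A)) < 1e-9) stop("cube not resolvable: degenerate corner")
    as.vector(solve(A, c(o1, o2, o3)))
  }
  corners_top <- corners_bot <- matrix(0, 4, 3)
  for (i in 1:4) {
    j <- i %% 4 + 1
    s1 <- sides[[i]]; s2 <- sides[[j]]
    corners_top[i, ] <- isect(s1$normal, s1$offset, s2$normal, s2$offset,
                              top$normal, top$offset)
    corners_bot[i, ] <- isect(s1$normal, s1$offset, s2$normal, s2$offset,
                              c(0, 0, 1), 0)
  }

  elen <- function(p, q) sqrt(sum((p - q)^2))
  horiz_edges <- function(corners, prefix) {
    ids <- character(4); axes <- character(4); len <- numeric(4)
    mid_y <- numeric(4); mid_x <- numeric(4)
    for (i in 1:4) {
      j <- i %% 4 + 1
      v <- corners[j, ] - corners[i, ]
      axes[i] <- if (abs(v[1]) >= abs(v[2])) "X" else "Y"
      len[i] <- elen(corners[i, ], corners[j, ])
      mid_y[i] <- (corners[i, 2] + corners[j, 2]) / 2
      mid_x[i] <- (corners[i, 1] + corners[j, 1]) / 2
    }
    for (a in c("X", "Y")) {
      k <- which(axes == a)
      if (length(k) != 2) stop("cube not resolvable: ambiguous edge axes")
      k <- if (a == "X") k[order(mid_y[k])] else k[order(mid_x[k])]
      base <- if (a == "X") 1 else 3
      ids[k] <- paste0(prefix, base:(base + 1))
    }
    data.frame(edge_id = ids, measured_cm = len)
  }
  u <- horiz_edges(corners_top, "U")
  d <- horiz_edges(corners_bot, "D")
  l <- data.frame(edge_id = paste0("L", 1:4),
                  measured_cm = vapply(1:4, function(i)
                    elen(corners_top[i, ], corners_bot[i, ]), 0))
  all_e <- rbind(u, d, l)
  res <- edge_measurements(all_e$edge_id, ref_cm, all_e$measured_cm)
  attr(res, "corners_top") <- corners_top
  attr(res, "corners_bottom") <- corners_bot
  res
}

# ---- precision polynomial ---------------------------------------------------

#' Fit the cubic precision polynomial
#'
#' Least-squares fit of a third-degree polynomial to (distance, dispersion)
#' pairs, modelling the platform's range precision as a function of distance.
#'
#' @param distance_m distances in meters (at least 4 distinct values).
#' @param sigma_cm measured dispersions (cm).
#' @return A list of class `precision_fit` with `coefficients` in the order
#'   `(a3, a2, a1, a0)` and `rms` residual.
#' @export
fit_precision_polynomial <- function(distance_m, sigma_cm) {
  stopifnot(length(distance_m) == length(sigma_cm))
  if (length(unique(distance_m)) < 4)
    stop("need at least 4 distinct distances for a cubic fit")
  fit <- lm(sigma_cm ~ distance_m + I(distance_m^2) + I(distance_m^3))
  cf <- unname(coef(fit))
  structure(list(coefficients = c(cf[4], cf[3], cf[2], cf[1]),
                 rms = sqrt(mean(fit$residuals^2))),
            class = "precision_fit")
}

#' @export
predict.precision_fit <- function(object, distance_m, ...) {
  noise_sigma(distance_m, object$coefficients)
}

#' @export
print.precision_fit <- function(x, ...) {
  cat(sprintf(
    "precision fit: sigma(d) = %.4f d^3 + %.4f d^2 + %.4f d + %.4f  (rms %.3g)\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3],
    x$coefficients[4], x$rms))
  invisible(x)
}

#' Simulated dispersion experiment
#'
#' Repeats the zero-incidence single-face distance measurement at a set of
#' sensor-to-target distances and reports the sample standard deviation of
#' the measured distance at each — the experiment whose results the precision
#' polynomial is fitted to. With repeat averaging active, the observed
#' dispersion is the single-shot noise divided by the square root of the
#' repeat count.
#'
#' @param scanner a [scanner_config()]; its `repeat_count` and noise model
#'   are used as configured.
#' @param distances_m sensor-to-face distances to probe (meters).
#' @param repetitions measurements per distance (>= 2).
#' @return Data frame with columns `distance_m` and `sigma_cm`.
#' @export
dispersion_experiment <- function(scanner, distances_m, repetitions = 142) {
  stopifnot(repetitions >= 2)
  sc <- build_target(include_disc = FALSE)
  narrow <- scanner
  narrow$aperture_deg <- 2 * scanner$angular_resolution_deg
  if (!is.null(scanner$rng_seed)) set.seed(scanner$rng_seed)
  sig <- vapply(distances_m, function(d) {
    calib <- platform_calibration(d_cm = d * 100, h_cm = 20, tilt_deg = 0)
    meas <- vapply(seq_len(repetitions), function(r) {
      p <- cast_profile(sc, narrow, calib, disc_angle_deg = 0, noise = TRUE)
      if (nrow(p) == 0) return(NA_real_)
      p$distance_cm[which.min(abs(p$beam_angle_deg))]
    }, 0)
    sd(meas, na.rm = TRUE)
  }, 0)
  data.frame(distance_m = distances_m, sigma_cm = sig)
}
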