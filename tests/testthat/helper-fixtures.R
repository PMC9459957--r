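# Shared fixtures: coarse scanner settings for fast simulated scans, and the
# random-geometry sampler for calibration studies.

# coarse beam grid keeps simulated test scans small
quick_scanner <- function(res = 0.25, repeats = 1, seed = NULL) {
  scanner_config(angular_resolution_deg = res, repeat_count = repeats,
                 rng_seed = seed)
}

sim_cloud <- function(sc, calib, step_deg = 5, scanner = quick_scanner(),
                      noise = FALSE) {
  scan <- simulate_scan(sc, scanner, turntable_config(step_deg = step_deg),
                        calib, noise = noise)
  reconstruct_scan(scan$profiles, calib)
}

# Random platform geometry with the target base (and so the disc surface) in
# view of the scan fan -- the physical prerequisite for height calibration.
draw_calibration_geometry <- function() {
  sc <- build_target()
  scn <- scanner_config(repeat_count = 1)
  repeat {
    d <- runif(1, 70, 300)
    h <- runif(1, -50, 50)
    ph <- runif(1, -5, 5)
    elev <- atan2(-h, d) * 180 / pi
    if (elev - ph <= -30 || elev - ph >= 30) next
    prof <- cast_profile(sc, scn, platform_calibration(d, h, ph), 0,
                         noise = FALSE)
    # both the target face and the disc surface must actually be in view
    # (and in range) for the procedure to apply
    if (sum(prof$label == "disc") >= 1 && sum(prof$label == "target") >= 10)
      return(list(d = d, h = h, tilt = ph))
  }
}

# signed volume of a closed triangle mesh (divergence theorem)
mesh_volume <- function(sc) {
  v <- sc$vertices
  f <- sc$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c2 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c2[, 3] - b[, 3] * c2[, 2]) +
      a[, 2] * (b[, 3] * c2[, 1] - b[, 1] * c2[, 3]) +
      a[, 3] * (b[, 1] * c2[, 2] - b[, 2] * c2[, 1])) / 6
}

# dense grid sampling of a cube surface (analytic, no scan)
cube_surface_points <- function(edge, n = 20) {
  g <- seq(0, edge, length.out = n)
  a <- edge / 2
  gg <- as.matrix(expand.grid(g, g))
  pts <- rbind(
    cbind(gg[, 1] - a, gg[, 2] - a, 0),
    cbind(gg[, 1] - a, gg[, 2] - a, edge),
    cbind(-a, gg[, 1] - a, gg[, 2]),
    cbind(a, gg[, 1] - a, gg[, 2]),
    cbind(gg[, 1] - a, -a, gg[, 2]),
    cbind(gg[, 1] - a, a, gg[, 2]))
  point_cloud(pts)
}

# tiny labeled synthetic plant: dense vertical stem line plus a leaf ring,
# separable in the descriptor space
toy_plant <- function(n_stem = 200, n_leaf = 200, seed = 1) {
  set.seed(seed)
  stem <- cbind(rnorm(n_stem, 0, 0.05), rnorm(n_stem, 0, 0.05),
                runif(n_stem, 0, 20))
  th <- runif(n_leaf, 0, 2 * pi)
  r <- runif(n_leaf, 4, 6)
  leaf <- cbind(r * cos(th), r * sin(th), runif(n_leaf, 8, 15))
  cl <- point_cloud(rbind(stem, leaf),
                    label = rep(c("stem", "leaf"), c(n_stem, n_leaf)))
  attr(cl, "n_leaves") <- 2L
  cl
}
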