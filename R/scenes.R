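# Parametric triangle-mesh scenes placed on the turntable disc. Scenes carry
# one label per triangle so the simulator can emit per-point ground truth.

#' Construct a scene
#'
#' A scene is a labeled triangle mesh placed on the disc: vertices in the disc
#' frame (cm, disc surface at z = 0, disc axis through the origin), 1-based
#' triangle indices, and one part label per triangle.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (cm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param labels character vector, one part label per triangle (recycled if
#'   length 1).
#' @return An object of class `scene`.
#' @export
scene <- function(vertices, faces, labels) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0)
    stopifnot(min(faces) >= 1, max(faces) <= nrow(vertices))
  if (length(labels) == 1) labels <- rep(labels, nrow(faces))
  if (length(labels) != nrow(faces))
    stop("every triangle must carry exactly one label")
  structure(list(vertices = vertices, faces = faces,
                 labels = as.character(labels)),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d vertices, %d triangles, parts: %s\n",
              nrow(x$vertices), nrow(x$faces),
              paste(unique(x$labels), collapse = ", ")))
  invisible(x)
}

merge_scenes <- function(...) {
  parts <- list(...)
  off <- 0L
  vs <- list(); fs <- list(); ls <- list()
  for (p in parts) {
    vs[[length(vs) + 1]] <- p$vertices
    fs[[length(fs) + 1]] <- p$faces + off
    ls[[length(ls) + 1]] <- p$labels
    off <- off + nrow(p$vertices)
  }
  scene(do.call(rbind, vs), do.call(rbind, fs), unlist(ls))
}

scene_max_z <- function(sc) max(sc$vertices[, 3])

# open cylindrical shell between z0 and z1 with per-slice radius
cylinder_shell <- function(radius_at, z0, z1, n_theta = 12, n_z = 8,
                           center = c(0, 0), label = "cylinder") {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zz <- seq(z0, z1, length.out = n_z + 1)
  rr <- vapply(zz, radius_at, 0)
  V <- do.call(rbind, lapply(seq_along(zz), function(i)
    cbind(center[1] + rr[i] * cos(th), center[2] + rr[i] * sin(th), zz[i])))
  F <- NULL
  for (i in seq_len(n_z)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    b <- (i - 1) * n_theta + seq_len(n_theta) %% n_theta + 1L
    F <- rbind(F, cbind(a, b, b + n_theta), cbind(a, b + n_theta, a + n_theta))
  }
  scene(V, F, label)
}

# flat disk (triangle fan) at height z
disk_mesh <- function(radius, z = 0, n_theta = 16, r_inner = 0,
                      label = "disc") {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  if (r_inner <= 0) {
    V <- rbind(c(0, 0, z), cbind(radius * cos(th), radius * sin(th), z))
    F <- cbind(1L, 1L + seq_len(n_theta), 1L + seq_len(n_theta) %% n_theta + 1L)
    return(scene(V, F, label))
  }
  Vi <- cbind(r_inner * cos(th), r_inner * sin(th), z)
  Vo <- cbind(radius * cos(th), radius * sin(th), z)
  V <- rbind(Vi, Vo)
  a <- seq_len(n_theta)
  b <- a %% n_theta + 1L
  F <- rbind(cbind(a, a + n_theta, b + n_theta), cbind(a, b + n_theta, b))
  scene(V, F, label)
}

#' Build the reference cube scene
#'
#' An axis-aligned cube resting on the disc surface, centred on the disc axis
#' — the reference object used to assess reconstruction accuracy.
#'
#' @param edge_cm cube edge length (cm), default the 5.5 cm reference cube.
#' @return A [scene()] with a single part `"cube"`.
#' @export
build_cube <- function(edge_cm = 5.5) {
  stopifnot(edge_cm > 0)
  a <- edge_cm / 2
  V <- as.matrix(expand.grid(x = c(-a, a), y = c(-a, a), z = c(0, edge_cm)))
  # vertex order from expand.grid: x fastest, then y, then z
  quad <- function(i, j, k, l) rbind(c(i, j, k), c(i, k, l))
  F <- rbind(
    quad(1, 2, 4, 3),  # bottom (z = 0)
    quad(5, 7, 8, 6),  # top
    quad(1, 3, 7, 5),  # x = -a
    quad(2, 6, 8, 4),  # x = +a
    quad(1, 5, 6, 2),  # y = -a
    quad(3, 4, 8, 7))  # y = +a
  scene(V, F, "cube")
}

#' Build the planar calibration-target scene
#'
#' A vertical, low-reflectance planar rectangle standing on the disc through
#' its centre O, facing the sensor (the face lies in the x = 0 plane). By
#' default the turntable surface itself is included as a horizontal disk at
#' z = 0, as it is in view during a real calibration sweep; the disc line in
#' the profile anchors the height estimate.
#'
#' @param height_cm target height (cm), default 40.
#' @param width_cm target width (cm), default 4.5.
#' @param include_disc include the turntable surface (part `"disc"`).
#' @param disc_radius_cm turntable radius (cm).
#' @return A [scene()] with parts `"target"` and optionally `"disc"`.
#' @export
build_target <- function(height_cm = 40, width_cm = 4.5, include_disc = TRUE,
                         disc_radius_cm = 15) {
  stopifnot(height_cm > 0, width_cm > 0)
  w <- width_cm / 2
  V <- rbind(c(0, -w, 0), c(0, w, 0), c(0, w, height_cm), c(0, -w, height_cm))
  F <- rbind(c(1, 2, 3), c(1, 3, 4))
  tgt <- scene(V, F, "target")
  if (!include_disc) return(tgt)
  merge_scenes(tgt, disk_mesh(disc_radius_cm, z = 0, n_theta = 24,
                              label = "disc"))
}

#' Random seedling parameters
#'
#' Draws a plausible parameter set for a parametric maize-like seedling:
#' a tapered vertical stem and a number of ribbon leaves attached at
#' increasing heights, each with its own azimuth, length, width and droop.
#' Total height is kept within the 10-40 cm range of young potted seedlings.
#'
#' @param stem_height_cm stem height above the soil surface (cm).
#' @param n_leaves number of leaves.
#' @param stem_radius_cm stem radius at the base (cm).
#' @param pot_height_cm pot height (cm); 0 for no pot.
#' @param seed integer seed; a fixed seed gives identical parameters.
#' @return A list of class `seedling_params`.
#' @export
seedling_params <- function(stem_height_cm = 25, n_leaves = 3,
                            stem_radius_cm = 0.35, pot_height_cm = 0,
                            seed = 1L) {
  if (stem_height_cm < 10 || stem_height_cm > 40)
    stop("stem_height_cm must lie in [10, 40] (young-seedling range)")
  stopifnot(stem_radius_cm > 0, n_leaves >= 0, pot_height_cm >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  leaves <- NULL
  if (n_leaves > 0) {
    attach_frac <- sort(runif(n_leaves, 0.25, 0.85))
    leaves <- data.frame(
      attach_frac = attach_frac,
      azimuth_deg = (seq_len(n_leaves) - 1) * 137.5 + runif(n_leaves, -20, 20),
      length_cm = runif(n_leaves, 0.45, 0.8) * stem_height_cm,
      max_width_cm = runif(n_leaves, 0.9, 1.8),
      droop = runif(n_leaves, 0.35, 0.65))
  }
  structure(list(stem_height_cm = stem_height_cm,
                 stem_radius_cm = stem_radius_cm,
                 n_leaves = as.integer(n_leaves), leaves = leaves,
                 pot_height_cm = pot_height_cm, pot_radius_cm = 4.5,
                 seed = as.integer(seed)),
            class = "seedling_params")
}

leaf_ribbon <- function(z_attach, azimuth_deg, length_cm, max_width_cm,
                        droop, n_seg = 12) {
  az <- deg2rad(azimuth_deg)
  u <- c(cos(az), sin(az), 0)         # outward midrib direction
  lat <- c(-sin(az), cos(az), 0)      # lateral (width) direction
  a0 <- deg2rad(55)                   # initial midrib elevation
  t <- seq(0, 1, length.out = n_seg + 1)
  rho <- length_cm * cos(a0) * t
  zz <- z_attach + length_cm * (sin(a0) * t - droop * t^2)
  w <- max_width_cm * sin(pi * pmin(t, 0.999)) / 2
  ctr <- cbind(rho * u[1], rho * u[2], zz)
  left <- ctr + outer(w, lat)
  right <- ctr - outer(w, lat)
  V <- rbind(left, right)
  n <- n_seg + 1
  a <- seq_len(n_seg)
  F <- rbind(cbind(a, a + n, a + 1), cbind(a + 1, a + n, a + n + 1))
  scene(V, F, "leaf")
}

#' Build a parametric seedling scene
#'
#' Constructs the mesh of a maize-like seedling from [seedling_params()]:
#' a tapered vertical cylinder (`"stem"`), ribbon leaves with parabolic droop
#' (`"leaf"`), and optionally a pot (`"pot"`) whose rim the stem emerges from.
#' Deterministic for a fixed parameter set.
#'
#' @param params a [seedling_params()] object.
#' @return A [scene()] with per-triangle ground-truth labels.
#' @export
build_seedling <- function(params) {
  stopifnot(inherits(params, "seedling_params"))
  z0 <- params$pot_height_cm
  r0 <- params$stem_radius_cm
  stem <- cylinder_shell(
    function(z) r0 * (1 - 0.45 * (z - z0) / params$stem_height_cm),
    z0, z0 + params$stem_height_cm, n_theta = 12, n_z = 10, label = "stem")
  parts <- list(stem)
  if (params$n_leaves > 0) {
    for (i in seq_len(params$n_leaves)) {
      lf <- params$leaves[i, ]
      parts[[length(parts) + 1]] <- leaf_ribbon(
        z0 + lf$attach_frac * params$stem_height_cm, lf$azimuth_deg,
        lf$length_cm, lf$max_width_cm, lf$droop)
    }
  }
  if (params$pot_height_cm > 0) {
    pot_side <- cylinder_shell(function(z) params$pot_radius_cm, 0, z0,
                               n_theta = 16, n_z = 2, label = "pot")
    soil <- disk_mesh(params$pot_radius_cm, z = z0, n_theta = 16,
                      label = "pot")
    parts <- c(parts, list(pot_side, soil))
  }
  do.call(merge_scenes, parts)
}
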