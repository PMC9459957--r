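# Per-point morphological descriptors for organ-level segmentation: the
# standard local eigenvalue family (linearity, planarity, sphericity,
# verticality) plus normalized height, radial distance to the stem axis and
# local density.

#' Estimate the stem axis
#'
#' The (x0, y0) of the vertical stem axis, taken as the horizontal centroid
#' of the points in the bottom slab of the cloud (optionally restricted to
#' stem-labeled points when labels are available).
#'
#' @param cloud a [point_cloud()].
#' @param slab_frac height fraction of the bottom slab, default 0.1.
#' @param use_labels restrict to `"stem"`-labeled points when present.
#' @return Numeric `c(x0, y0)`.
#' @export
stem_axis_estimate <- function(cloud, slab_frac = 0.1, use_labels = TRUE) {
  p <- cloud$points
  if (nrow(p) == 0) stop("no points")
  keep <- rep(TRUE, nrow(p))
  if (use_labels && !is.null(cloud$label) && any(cloud$label == "stem"))
    keep <- cloud$label == "stem"
  z <- p[keep, 3]
  zcut <- min(z) + slab_frac * max(diff(range(z)), 1e-9)
  slab <- keep
  slab[keep] <- z <= zcut
  c(x0 = mean(p[slab, 1]), y0 = mean(p[slab, 2]))
}

#' Extract per-point geometric descriptors
#'
#' For each point, the covariance of its spherical neighbourhood gives
#' eigenvalues l1 >= l2 >= l3 and the associated eigenvectors, from which the
#' standard shape descriptors are formed: linearity `(l1-l2)/l1`, planarity
#' `(l2-l3)/l1`, sphericity `l3/l1`, verticality of the principal direction
#' (`|e1 . z|`, near 1 on a vertical stem) and of the normal direction
#' (`|e3 . z|`, near 1 on a horizontal surface). Added to these are the
#' normalized height `z/max(z)`, the radial distance to the estimated stem
#' axis, and the local point density. Points with degenerate neighbourhoods
#' (< 3 neighbours) get `NA` eigen-features and are flagged.
#'
#' @param cloud a [point_cloud()] with at least 10 points.
#' @param neighborhood_radius spherical neighbourhood radius (cm).
#' @param axis optional stem axis `c(x0, y0)`; estimated when `NULL`.
#' @return A data frame, one row per point: `norm_height`, `radial_cm`,
#'   `linearity`, `planarity`, `sphericity`, `vert_axis`, `vert_normal`,
#'   `density`, `degenerate`.
#' @export
extract_features <- function(cloud, neighborhood_radius = 1, axis = NULL) {
  p <- cloud$points
  if (nrow(p) < 10) stop("need at least 10 points for feature extraction")
  stopifnot(neighborhood_radius > 0)
  eg <- cpp_local_eigen(p, neighborhood_radius)
  l1 <- pmax(eg[, 1], 1e-300); l2 <- pmax(eg[, 2], 0); l3 <- pmax(eg[, 3], 0)
  if (is.null(axis)) axis <- stem_axis_estimate(cloud, use_labels = FALSE)
  zmax <- max(p[, 3])
  zmin <- min(p[, 3])
  out <- data.frame(
    norm_height = (p[, 3] - zmin) / max(zmax - zmin, 1e-9),
    radial_cm = sqrt((p[, 1] - axis[1])^2 + (p[, 2] - axis[2])^2),
    linearity = (l1 - l2) / l1,
    planarity = (l2 - l3) / l1,
    sphericity = l3 / l1,
    vert_axis = abs(eg[, 6]),
    vert_normal = abs(eg[, 9]),
    density = eg[, 10] / (4 / 3 * pi * neighborhood_radius^3),
    degenerate = eg[, 10] < 3)
  out
}
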