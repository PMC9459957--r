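# Pre-processing and scalar traits: statistical outlier removal, Z-axis
# cropping (pot removal), plant height and occupied-voxel volume.

#' Statistical outlier removal
#'
#' Removes points whose mean distance to their k nearest neighbours exceeds
#' the global mean of that statistic by more than `std_ratio` standard
#' deviations. Never adds points; intensity and labels of the survivors are
#' preserved index-aligned.
#'
#' @param cloud a [point_cloud()].
#' @param k_neighbors neighbourhood size (>= 1).
#' @param std_ratio threshold in standard deviations (> 0).
#' @return The filtered [point_cloud()]. If the cloud has fewer than
#'   `k_neighbors + 1` points it is returned unchanged with a warning.
#' @export
remove_outliers <- function(cloud, k_neighbors = 20, std_ratio = 2) {
  stopifnot(k_neighbors >= 1, std_ratio > 0)
  n <- n_points(cloud)
  if (n < k_neighbors + 1) {
    warning("too few points for outlier removal; cloud returned unchanged")
    return(cloud)
  }
  md <- cpp_knn_mean_dist(cloud$points, as.integer(k_neighbors))
  keep <- md <= mean(md) + std_ratio * sd(md)
  subset_cloud(cloud, keep)
}

#' Crop a cloud along the Z axis
#'
#' Limits the working volume on the vertical axis, removing the pot below
#' `z_min` and any stray returns above `z_max`.
#'
#' @param cloud a [point_cloud()].
#' @param z_min,z_max inclusive bounds (cm); `z_min < z_max`.
#' @return The cropped [point_cloud()].
#' @export
crop_pot <- function(cloud, z_min = -Inf, z_max = Inf) {
  stopifnot(z_min < z_max)
  z <- cloud$points[, 3]
  subset_cloud(cloud, z >= z_min & z <= z_max)
}

#' Plant height
#'
#' The height trait is the maximum Z over the (pot-cropped) cloud, with the
#' disc surface at z = 0.
#'
#' @param cloud a non-empty [point_cloud()].
#' @return Height in cm.
#' @export
plant_height <- function(cloud) {
  if (n_points(cloud) == 0) stop("no points: cannot measure height")
  max(cloud$points[, 3])
}

#' Voxel grid specification
#'
#' Axis-aligned voxelization used by the volume trait: each occupied voxel
#' contributes `volume_coeff` cubic centimeters. The default coefficient is
#' the experimentally calibrated 2.5e-3 cm^3 per occupied voxel; by default
#' the voxel edge is the cube root of the coefficient, so the estimate
#' converges to the geometric volume for densely sampled solids.
#'
#' @param voxel_edge_cm voxel edge length (cm); default `volume_coeff^(1/3)`.
#' @param volume_coeff cm^3 contributed per occupied voxel.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(voxel_edge_cm = NULL, volume_coeff = 2.5e-3) {
  stopifnot(volume_coeff > 0)
  if (is.null(voxel_edge_cm)) voxel_edge_cm <- volume_coeff^(1 / 3)
  stopifnot(voxel_edge_cm > 0)
  structure(list(voxel_edge_cm = voxel_edge_cm, volume_coeff = volume_coeff),
            class = "voxel_grid")
}

#' Occupied-voxel volume
#'
#' Counts the distinct occupied voxels of an axis-aligned grid anchored at
#' the cloud's minimum corner and returns `volume_coeff` times that count.
#'
#' @param cloud a [point_cloud()].
#' @param grid a [voxel_grid()].
#' @return Volume in cm^3 (0 for an empty cloud).
#' @export
voxel_volume <- function(cloud, grid = voxel_grid()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (n_points(cloud) == 0) return(0)
  p <- cloud$points
  anchor <- apply(p, 2, min)
  idx <- floor(sweep(p, 2, anchor) / grid$voxel_edge_cm + 1e-9)
  # pack the three non-negative indices into one exact double key
  m <- apply(idx, 2, max) + 1
  key <- (idx[, 1] * m[2] + idx[, 2]) * m[3] + idx[, 3]
  occupied <- length(unique(key))
  grid$volume_coeff * occupied
}
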