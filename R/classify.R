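# Stem/leaf organ classification: plant-wise 60/20/20 split, Random Forest
# on the geometric descriptors, and the ascending virtual-ring stem filter.

#' Split a scan collection into train / tune / validate sets
#'
#' Partitions whole scans (all points of a plant stay together) into
#' training, tuning and validation subsets, by default 60/20/20. Scans are
#' first routed into two growth stages — early (shoot up to the third leaf)
#' and late (the rest) — by their leaf-count metadata, and each stage is
#' partitioned separately.
#'
#' @param scans list of labeled [point_cloud()] objects; each may carry an
#'   `n_leaves` attribute for stage routing (scans without it go to one pool).
#' @param train_frac,tune_frac fractions for training and tuning; validation
#'   takes the rest. Training size is floored, the remainder split evenly.
#' @param seed integer seed; a fixed seed gives an identical partition.
#' @return A list with elements `train`, `tune`, `validate` (lists of scans)
#'   and `stage` (factor per input scan).
#' @export
split_dataset <- function(scans, train_frac = 0.6, tune_frac = 0.2,
                          seed = 1L) {
  stopifnot(train_frac > 0, tune_frac > 0, train_frac + tune_frac < 1)
  leaves <- vapply(scans, function(s) {
    nl <- attr(s, "n_leaves")
    if (is.null(nl)) NA_integer_ else as.integer(nl)
  }, 1L)
  stage <- factor(ifelse(is.na(leaves) | leaves <= 3, "early", "late"),
                  levels = c("early", "late"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train <- tune <- validate <- integer(0)
  for (st in levels(stage)) {
    idx <- which(stage == st)
    n <- length(idx)
    if (n == 0) next
    if (n < 5) stop("need at least 5 scans per stage, got ", n, " (", st, ")")
    idx <- sample(idx)
    n_train <- floor(train_frac * n)
    n_tune <- floor((n - n_train) / 2)
    train <- c(train, idx[seq_len(n_train)])
    tune <- c(tune, idx[n_train + seq_len(n_tune)])
    validate <- c(validate, idx[(n_train + n_tune + 1):n])
  }
  list(train = scans[train], tune = scans[tune], validate = scans[validate],
       stage = stage)
}

scan_feature_table <- function(cloud, neighborhood_radius = 1,
                               max_points = 4000, seed = 1L) {
  if (is.null(cloud$label) || !any(cloud$label %in% c("stem", "leaf")))
    stop("scan has no stem/leaf labels")
  cl <- subset_cloud(cloud, cloud$label %in% c("stem", "leaf"))
  if (n_points(cl) > max_points) {
    set.seed(seed)
    cl <- subset_cloud(cl, sample.int(n_points(cl), max_points))
  }
  f <- extract_features(cl, neighborhood_radius)
  f$label <- factor(cl$label, levels = c("stem", "leaf"))
  f[!f$degenerate, setdiff(names(f), "degenerate")]
}

#' Train the stem/leaf Random Forest classifier
#'
#' Extracts the geometric descriptors of every training scan, fits Random
#' Forests over a small hyperparameter grid (number of trees and maximum
#' depth) and keeps the configuration with the best point accuracy on the
#' tuning scans.
#'
#' @param train,tune lists of labeled [point_cloud()] scans.
#' @param neighborhood_radius descriptor neighbourhood radius (cm).
#' @param grid data frame of candidate hyperparameters with columns
#'   `num_trees` and `max_depth` (0 = unlimited).
#' @param max_points_per_scan per-scan subsample cap for training features.
#' @param seed integer seed; fixed seed gives a deterministic model.
#' @return A list of class `organ_classifier` with the fitted `ranger`
#'   forest, the chosen hyperparameters and the tuning accuracies.
#' @export
train_classifier <- function(train, tune, neighborhood_radius = 1,
                             grid = expand.grid(num_trees = c(50, 100, 200),
                                                max_depth = c(8, 16, 0)),
                             max_points_per_scan = 4000, seed = 1L) {
  stopifnot(length(train) >= 1, length(tune) >= 1)
  tr <- do.call(rbind, lapply(train, scan_feature_table,
                              neighborhood_radius = neighborhood_radius,
                              max_points = max_points_per_scan, seed = seed))
  if (length(unique(tr$label)) < 2)
    stop("training set must contain both stem and leaf points")
  tu <- do.call(rbind, lapply(tune, scan_feature_table,
                              neighborhood_radius = neighborhood_radius,
                              max_points = max_points_per_scan, seed = seed))
  acc <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- ranger::ranger(
      label ~ ., data = tr, num.trees = grid$num_trees[i],
      max.depth = grid$max_depth[i], seed = seed, num.threads = 1)
    pred <- predict(fits[[i]], data = tu, num.threads = 1)$predictions
    acc[i] <- mean(pred == tu$label)
  }
  best <- which.max(acc)
  structure(list(forest = fits[[best]],
                 num_trees = grid$num_trees[best],
                 max_depth = grid$max_depth[best],
                 tune_accuracy = acc,
                 neighborhood_radius = neighborhood_radius,
                 seed = as.integer(seed)),
            class = "organ_classifier")
}

#' @export
print.organ_classifier <- function(x, ...) {
  cat(sprintf(
    "organ classifier: %d trees, max depth %s, tune accuracy %.3f\n",
    x$num_trees, if (x$max_depth == 0) "unlimited" else x$max_depth,
    max(x$tune_accuracy)))
  invisible(x)
}

#' Classify the points of a cloud into stem and leaf
#'
#' @param model an [train_classifier()] model.
#' @param cloud a [point_cloud()].
#' @return The cloud with predicted per-point labels (`"stem"`/`"leaf"`);
#'   points with degenerate neighbourhoods inherit the label of the nearest
#'   classified point.
#' @export
classify_organs <- function(model, cloud) {
  stopifnot(inherits(model, "organ_classifier"))
  f <- extract_features(cloud, model$neighborhood_radius)
  lab <- rep(NA_character_, nrow(f))
  good <- !f$degenerate
  if (!any(good)) stop("no point has a usable neighbourhood; ",
                       "increase the descriptor radius")
  pred <- predict(model$forest, data = f[good, , drop = FALSE],
                  num.threads = 1)$predictions
  lab[good] <- as.character(pred)
  if (any(!good)) {
    gp <- cloud$points[good, , drop = FALSE]
    for (i in which(!good)) {
      nn <- which.min(colSums((t(gp) - cloud$points[i, ])^2))
      lab[i] <- lab[good][nn]
    }
  }
  point_cloud(cloud$points, intensity = cloud$intensity, label = lab,
              frame = cloud$frame)
}

#' Virtual-ring stem filter
#'
#' Sweeps a ring of fixed radius up the (vertical) stem axis from the base of
#' the plant to its highest point: any stem-labeled point farther from the
#' axis than the ring radius is relabeled leaf. Leaf labels are never changed
#' to stem, so the filter is idempotent and never decreases the leaf count.
#'
#' @param cloud a labeled [point_cloud()].
#' @param radius ring radius, in the cloud's units.
#' @param axis stem axis `c(x0, y0)`; estimated from the stem-labeled points
#'   of the bottom height slab when `NULL`.
#' @return The relabeled [point_cloud()]. When the cloud has no stem-labeled
#'   points it is returned unchanged with a warning.
#' @export
ring_filter <- function(cloud, radius = 0.0015, axis = NULL) {
  stopifnot(radius > 0)
  if (is.null(cloud$label) || !any(cloud$label == "stem")) {
    warning("no stem-labeled points; cloud returned unchanged")
    return(cloud)
  }
  if (is.null(axis)) axis <- stem_axis_estimate(cloud, use_labels = TRUE)
  r <- sqrt((cloud$points[, 1] - axis[1])^2 + (cloud$points[, 2] - axis[2])^2)
  lab <- cloud$label
  lab[lab == "stem" & r > radius] <- "leaf"
  point_cloud(cloud$points, intensity = cloud$intensity, label = lab,
              frame = cloud$frame)
}

#' Point-wise classification accuracy
#'
#' @param predicted,truth equal-length label vectors.
#' @return Percentage of matching labels.
#' @export
label_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  100 * mean(as.character(predicted) == as.character(truth))
}

#' Stem precision of a predicted labeling
#'
#' Fraction of stem-labeled points that are truly stem — the quantity the
#' virtual-ring filter is designed to increase.
#'
#' @param predicted,truth equal-length label vectors.
#' @return Precision in `[0, 1]` (`NaN` when nothing is labeled stem).
#' @export
stem_precision <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  pred_stem <- as.character(predicted) == "stem"
  if (!any(pred_stem)) return(NaN)
  mean(as.character(truth)[pred_stem] == "stem")
}
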