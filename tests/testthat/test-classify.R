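test_that("plant-wise splits honour the 60/20/20 fractions", {
  scans <- lapply(1:10, function(i) toy_plant(seed = i))
  sp <- split_dataset(scans, seed = 4)
  expect_length(sp$train, 6)
  expect_length(sp$tune, 2)
  expect_length(sp$validate, 2)
  # identical partition for a fixed seed; disjoint and exhaustive
  sp2 <- split_dataset(scans, seed = 4)
  expect_identical(lapply(sp$train, `[[`, "points"),
                   lapply(sp2$train, `[[`, "points"))
  key <- function(s) paste(s$points[1, ], collapse = ",")
  all_keys <- sort(vapply(c(sp$train, sp$tune, sp$validate), key, ""))
  expect_equal(all_keys, sort(vapply(scans, key, "")))
  expect_error(split_dataset(scans[1:3]), "at least 5")
})

test_that("scans route into early and late stages by leaf count", {
  scans <- lapply(1:12, function(i) {
    s <- toy_plant(seed = i)
    attr(s, "n_leaves") <- if (i <= 6) 2L else 5L
    s
  })
  sp <- split_dataset(scans, seed = 1)
  expect_equal(as.vector(table(sp$stage)), c(6, 6))
  expect_length(sp$train, 6)  # 3 early + 3 late
})

test_that("a separable toy benchmark is classified perfectly", {
  scans <- lapply(1:6, function(i) toy_plant(seed = i))
  sp <- split_dataset(scans, seed = 2)
  model <- train_classifier(sp$train, sp$tune, neighborhood_radius = 1,
                            grid = data.frame(num_trees = 50, max_depth = 8),
                            seed = 7)
  v <- sp$validate[[1]]
  pred <- classify_organs(model, point_cloud(v$points))
  expect_equal(label_accuracy(pred$label, v$label), 100)
  # determinism of the fitted model
  model2 <- train_classifier(sp$train, sp$tune, neighborhood_radius = 1,
                             grid = data.frame(num_trees = 50, max_depth = 8),
                             seed = 7)
  pred2 <- classify_organs(model2, point_cloud(v$points))
  expect_identical(pred$label, pred2$label)
})

test_that("permuted training labels drop accuracy to the class prior", {
  scans <- lapply(1:6, function(i) toy_plant(seed = i))
  sp <- split_dataset(scans, seed = 2)
  set.seed(99)
  shuffled <- lapply(sp$train, function(s)
    point_cloud(s$points, label = sample(s$label)))
  model <- train_classifier(shuffled, sp$tune, neighborhood_radius = 1,
                            grid = data.frame(num_trees = 50, max_depth = 8),
                            seed = 7)
  v <- sp$validate[[1]]
  acc <- label_accuracy(classify_organs(model, point_cloud(v$points))$label,
                        v$label)
  prior <- 100 * max(table(v$label)) / length(v$label)
  expect_lt(abs(acc - prior), 15)
})

test_that("single-class training sets are rejected", {
  stem_only <- point_cloud(matrix(runif(600, 0, 5), ncol = 3),
                           label = rep("stem", 200))
  expect_error(train_classifier(list(stem_only), list(stem_only)),
               "both stem and leaf")
})

test_that("the virtual ring relabels off-axis stem points and only those", {
  cl <- toy_plant(seed = 3)
  # all true stem points lie within the ring: labels unchanged
  same <- ring_filter(cl, radius = 1)
  expect_identical(same$label, cl$label)
  # an off-axis point labeled stem gets relabeled leaf
  bad <- point_cloud(rbind(cl$points, c(10, 0, 5)),
                     label = c(cl$label, "stem"))
  filt <- ring_filter(bad, radius = 1)
  expect_equal(filt$label[length(filt$label)], "leaf")
  # idempotence and leaf-count monotonicity
  twice <- ring_filter(filt, radius = 1)
  expect_identical(twice$label, filt$label)
  expect_gte(sum(filt$label == "leaf"), sum(bad$label == "leaf"))
  expect_warning(ring_filter(point_cloud(matrix(1:9, 3),
                                         label = rep("leaf", 3)), 1),
                 "no stem")
})

test_that("ring filtering strictly improves corrupted stem precision", {
  cl <- toy_plant(n_stem = 300, n_leaf = 300, seed = 6)
  set.seed(10)
  lab <- cl$label
  flip <- sample(which(lab == "leaf"), 15)  # 5% of leaf points called stem
  lab[flip] <- "stem"
  noisy <- point_cloud(cl$points, label = lab)
  filt <- ring_filter(noisy, radius = 1)
  expect_gt(stem_precision(filt$label, cl$label),
            stem_precision(noisy$label, cl$label))
  expect_equal(stem_precision(filt$label, cl$label), 1)
})

test_that("accuracy and precision summaries are plain confusion arithmetic", {
  expect_equal(label_accuracy(c("a", "b"), c("a", "b")), 100)
  expect_equal(label_accuracy(c("a", "b"), c("a", "a")), 50)
  truth <- rep(c("stem", "leaf", "stem", "leaf"), c(40, 45, 10, 5))
  pred <- rep(c("stem", "leaf", "leaf", "stem"), c(40, 45, 10, 5))
  expect_equal(label_accuracy(pred, truth), 85)
  expect_equal(stem_precision(pred, truth), 40 / 45)
  expect_error(label_accuracy("a", c("a", "b")), "equal length")
})
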