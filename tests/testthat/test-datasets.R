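test_that("equal-width binning follows the closed-upper-edge rule", {
  ds <- label_only_dataset(0:99)
  ds <- assign_bins(ds, 20)
  expect_equal(ds$label_bins[labels(ds) == 0], 0L)
  expect_equal(ds$label_bins[labels(ds) == 99], 19L)
  expect_equal(ds$label_bins[labels(ds) == 50], 10L)
  expect_true(all(ds$label_bins >= 0 & ds$label_bins < 20))

  one <- assign_bins(label_only_dataset(c(3L, 9L, 4L)), 1)
  expect_true(all(one$label_bins == 0L))

  expect_error(assign_bins(label_only_dataset(rep(5L, 10)), 4), "labels equal")

  full <- assign_bins(label_only_dataset(rep(1:63, 3)), 8)
  expect_equal(sort(unique(full$label_bins)), 0:7)
  # contiguity: label order implies bin order
  ord <- order(labels(full))
  expect_true(!is.unsorted(full$label_bins[ord]))
})

test_that("stratified test splits reproduce the published design sizes", {
  set.seed(401)
  ds <- label_only_dataset(sample(1:63, 3585, replace = TRUE))
  parts <- stratified_test_split(ds, split_spec(n_bins = 8, per_bin = 15, seed = 2))
  expect_equal(length(parts$test), 120)
  expect_equal(length(parts$remainder), 3465)
  expect_setequal(c(dataset_ids(parts$test), dataset_ids(parts$remainder)),
                  dataset_ids(ds))
  expect_equal(as.numeric(table(parts$test$label_bins)), rep(15, 8))

  seals <- label_only_dataset(sample(0:400, 11087, replace = TRUE), prefix = "seal")
  p2 <- stratified_test_split(seals, split_spec(20, 5, seed = 3))
  expect_equal(length(p2$test), 100)
  expect_equal(length(p2$remainder), 10987)

  none <- stratified_test_split(ds, split_spec(8, 0, seed = 4))
  expect_equal(length(none$test), 0)
  expect_identical(dataset_ids(none$remainder), dataset_ids(ds))

  sparse <- label_only_dataset(c(rep(1L, 30), 60L))
  expect_error(stratified_test_split(sparse, split_spec(4, 5, seed = 1)),
               "bin .* only")
})

test_that("stratified splits are deterministic partitions for random datasets", {
  for (rep in 1:25) {
    n <- sample(60:200, 1)
    ds <- label_only_dataset(sample(0:50, n, replace = TRUE),
                             prefix = sprintf("r%02d", rep))
    sp <- split_spec(n_bins = sample(2:5, 1), per_bin = 2, seed = rep)
    parts <- try(stratified_test_split(ds, sp), silent = TRUE)
    if (inherits(parts, "try-error")) next  # an underpopulated bin is legal here
    expect_equal(length(parts$test), sp$n_bins * sp$per_bin)
    expect_setequal(c(dataset_ids(parts$test), dataset_ids(parts$remainder)),
                    dataset_ids(ds))
    expect_length(intersect(dataset_ids(parts$test),
                            dataset_ids(parts$remainder)), 0)
    again <- stratified_test_split(ds, sp)
    expect_identical(dataset_ids(again$test), dataset_ids(parts$test))
  }
})

test_that("train/validation split uses the floor rule and is seeded", {
  ds <- label_only_dataset(sample(1:40, 3465, replace = TRUE))
  tv <- train_val_split(ds, 0.8, seed = 5)
  expect_equal(length(tv$train), 2772)
  expect_equal(length(tv$validation), 693)
  expect_setequal(c(dataset_ids(tv$train), dataset_ids(tv$validation)),
                  dataset_ids(ds))

  small <- train_val_split(label_only_dataset(1:10), 0.8, seed = 6)
  expect_equal(length(small$train), 8)
  expect_equal(length(small$validation), 2)

  expect_identical(dataset_ids(train_val_split(ds, 0.8, seed = 5)$train),
                   dataset_ids(tv$train))
  expect_error(train_val_split(label_only_dataset(1L), 0.8), "two items")
})

test_that("augmentation reaches target size and never changes the label", {
  im <- generate_dot_scene(clean_dot_spec(), 8, 21)
  idp <- identity_policy(64, 64)
  same <- augment(im, idp, seed = 1)
  expect_equal(same$pixels, im$pixels, tolerance = 1e-12)
  expect_equal(same$label, im$label)

  pol <- augmentation_policy(target_height = 48, target_width = 56)
  out <- augment(im, pol, seed = 2)
  expect_equal(dim(out$pixels), c(48L, 56L))
  expect_equal(out$label, im$label)

  # seeded determinism of the random draw
  expect_identical(augment(im, pol, seed = 2)$pixels, out$pixels)

  # horizontal flip leaves the count oracle unchanged
  flipped <- augment(im, augmentation_policy(horizontal_flip_probability = 1,
                                             lighting_jitter_range = c(1, 1),
                                             warp_magnitude = 0,
                                             max_zoom_fraction = 0), seed = 3)
  expect_equal(flipped$pixels, im$pixels[, ncol(im$pixels):1], tolerance = 1e-12)
})

test_that("sampled augmentations preserve the component-count oracle", {
  skip_if_not_installed("EBImage")
  spec <- clean_dot_spec()
  pol <- augmentation_policy()
  failures <- 0L
  withr::with_seed(77, {
    for (s in 1:100) {
      im <- generate_dot_scene(spec, sample(0:25, 1), 5000 + s)
      for (k in 1:10) {
        aug <- augment(im, pol)
        if (cc_count(aug$pixels) != im$label) failures <- failures + 1L
      }
    }
  })
  expect_equal(failures, 0L)
})
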