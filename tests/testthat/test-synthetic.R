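test_that("dot scenes are seeded, bounded and carry exact labels", {
  spec <- dot_scene_spec()
  a <- generate_dot_scene(spec, 25, 1)
  b <- generate_dot_scene(spec, 25, 1)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$id, b$id)
  expect_false(identical(a$pixels, generate_dot_scene(spec, 25, 2)$pixels))

  empty <- generate_dot_scene(spec, 0, 7)
  expect_equal(empty$label, 0L)
  expect_equal(sum(empty$meta$objects$type == "counted"), 0)

  expect_error(generate_dot_scene(spec, 31, 1), "count_range")
  expect_error(generate_dot_scene(spec, -1, 1), "count_range")
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
})

test_that("connected components of clean dot scenes equal the label", {
  skip_if_not_installed("EBImage")
  spec <- clean_dot_spec()
  for (count in c(1, 5, 12, 25)) {
    for (seed in 1:3) {
      im <- generate_dot_scene(spec, count, seed)
      expect_equal(cc_count(im$pixels), count,
                   info = sprintf("count %d seed %d", count, seed))
    }
  }
})

test_that("object masks cover the counted objects only", {
  im <- generate_dot_scene(dot_scene_spec(distractor_count_range = c(2L, 2L)), 6, 5)
  m_obj <- object_mask(im, "counted")
  m_dis <- object_mask(im, "distractor")
  expect_true(sum(m_obj) > 0 && sum(m_dis) > 0)
  expect_equal(sum(m_obj & m_dis), 0)
  # bright pixels inside masks, background outside darker on average
  expect_gt(mean(im$pixels[m_obj]), mean(im$pixels[!m_obj & !m_dis]))
})

test_that("ring images are seeded and respect the AGC geometry", {
  spec <- ring_image_spec()
  a <- generate_ring_image(spec, 20, 3)
  expect_identical(a$pixels, generate_ring_image(spec, 20, 3)$pixels)
  expect_equal(a$label, 20L)

  one <- generate_ring_image(spec, 1, 3)
  expect_equal(ring_peak_count(one), 1)
  expect_equal(ring_peak_count(a), 20)

  expect_error(generate_ring_image(spec, 0, 1), "ring_count_range")
  expect_error(ring_image_spec(image_height = 32, image_width = 32,
                               ring_count_range = c(1, 28)),
               "half-width")
  expect_error(ring_image_spec(ring_count_range = c(1, 64)), "\\[1, 63\\]")
})

test_that("radial peak oracle matches the label across counts", {
  spec <- ring_image_spec()
  for (count in c(3, 10, 28)) {
    im <- generate_ring_image(spec, count, count + 11)
    expect_equal(ring_peak_count(im), count, info = paste("count", count))
  }
})

test_that("make_dataset reproduces the requested label distribution", {
  spec <- dot_scene_spec(count_range = c(0L, 99L), image_height = 12L,
                         image_width = 12L, overlap_allowed = TRUE,
                         distractor_count_range = c(0L, 0L))
  w5 <- stats::setNames(1, 5)
  d5 <- make_dataset(dot_scene_spec(), 50, w5, seed = 3)
  expect_true(all(labels(d5) == 5))

  w <- skewed_count_weights(c(0L, 99L), rate = 3)
  big <- make_dataset(spec, 10000, w, seed = 4)
  lab <- labels(big)
  expect_identical(lab, labels(make_dataset(spec, 10000, w, seed = 4)))

  p <- w / sum(w)
  mu <- sum(as.integer(names(w)) * p)
  sigma <- sqrt(sum((as.integer(names(w)) - mu)^2 * p))
  expect_lt(abs(mean(lab) - mu), 3 * sigma / sqrt(length(lab)))

  # distributional control: goodness of fit not rejected at alpha = 0.01
  obs <- table(factor(lab, levels = 0:99))
  gof <- stats::chisq.test(as.numeric(obs), p = p)
  expect_gt(gof$p.value, 0.01)

  expect_error(make_dataset(spec, 0, w), "n_images")
  expect_error(make_dataset(spec, 5, stats::setNames(c(0, 0), 1:2)),
               "not all zero")
})

test_that("label corruption is undercount-only and statistically calibrated", {
  base <- label_only_dataset(rep(10L, 10000))
  noiseless <- corrupt_labels(base, label_noise_model(corruption_probability = 0),
                              seed = 5)
  expect_identical(labels(noiseless), labels(base))

  forced <- corrupt_labels(label_only_dataset(rep(10L, 4)),
                           label_noise_model(1, c(0.5, 0.5)), seed = 5)
  expect_true(all(labels(forced) == 5L))
  expect_true(all(vapply(forced$items, function(it) it$flags$noisy, logical(1))))

  mc <- corrupt_labels(base, label_noise_model(1, c(0.3, 0.9)), seed = 6)
  ratio <- labels(mc) / true_labels(mc)
  expect_true(all(labels(mc) <= true_labels(mc)))
  expect_true(all(labels(mc) >= 0))
  # floor(10 * f) / 10 has mean ~ mean(f) - 0.05 for f ~ U(0.3, 0.9)
  se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 0.55), 3 * se)

  # corruption coin false => label untouched
  half <- corrupt_labels(base, label_noise_model(0.5, c(0.3, 0.9)), seed = 7)
  clean_idx <- !vapply(half$items, function(it) it$flags$noisy, logical(1))
  expect_true(all(labels(half)[clean_idx] == 10L))
})

test_that("the relabelling oracle returns true counts or the unidentifiable signal", {
  ok <- labelled_image(NULL, 8, "a", true_label = 12)
  expect_identical(oracle_relabel(ok), 12L)
  flagged <- labelled_image(NULL, 8, "b", true_label = 12, unidentifiable = TRUE)
  expect_identical(oracle_relabel(flagged), NA_integer_)
  no_meta <- labelled_image(NULL, 8, "c")
  no_meta$true_label <- NULL
  expect_error(oracle_relabel(no_meta), "true-label")

  flags <- rep(FALSE, 200); flags[sample.int(200, 35)] <- TRUE
  ds <- label_only_dataset(rep(10L, 200), unidentifiable = flags)
  res <- vapply(ds$items, oracle_relabel, integer(1))
  expect_equal(sum(is.na(res)), 35)
})

test_that("datasets round-trip through PNG images and CSV manifests", {
  ds <- tiny_dot_dataset(4, seed = 9)
  ds <- corrupt_labels(ds, label_noise_model(1, c(0.5, 0.5)), seed = 2)
  dir <- withr::local_tempdir()
  write_count_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  man <- utils::read.csv(file.path(dir, "labels.csv"))
  expect_identical(names(man),
                   c("image_path", "count", "true_count", "unidentifiable", "noisy"))
  back <- read_count_dataset(dir)
  expect_identical(labels(back), labels(ds))
  expect_identical(true_labels(back), true_labels(ds))
  expect_equal(dim(back$items[[1]]$pixels), dim(ds$items[[1]]$pixels))
  # 8-bit quantisation only
  expect_lt(max(abs(back$items[[1]]$pixels - ds$items[[1]]$pixels)), 1 / 255)
})
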