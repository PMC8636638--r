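test_that("huber loss matches its closed form on both branches", {
  expect_equal(huber_loss(c(3, 4), c(3, 4)), 0)
  expect_equal(huber_loss(0.5, 0), 0.125)
  expect_equal(huber_loss(3, 0), 2.5)
  expect_equal(huber_loss(c(0.5, 3), c(0, 0)), 1.3125)
  # continuity at the branch point
  expect_equal(huber_loss(1 - 1e-12, 0), 0.5, tolerance = 1e-9)
  expect_equal(huber_loss(1 + 1e-12, 0), 0.5, tolerance = 1e-9)
  expect_error(huber_loss(numeric(0), numeric(0)), "nonempty")
  expect_error(huber_loss(1:3, 1:2), "equal length")
})

test_that("huber loss agrees with an element-loop oracle and grows subquadratically", {
  loop_huber <- function(p, t) {
    acc <- 0
    for (i in seq_along(p)) {
      r <- abs(t[i] - p[i])
      acc <- acc + if (r < 1) 0.5 * r^2 else r - 0.5
    }
    acc / length(p)
  }
  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(1:40, 1)
      p <- rnorm(n, sd = 5); t <- rnorm(n, sd = 5)
      expect_equal(huber_loss(p, t), loop_huber(p, t), tolerance = 1e-12)
    }
  })
  # monotone nondecreasing in |r|, subquadratic in the tail
  r <- seq(0, 50, by = 0.01)
  l <- vapply(r, function(x) huber_loss(x, 0), numeric(1))
  expect_true(all(diff(l) >= 0))
  expect_lt(huber_loss(1e6, 0) / 1e12, 1e-5)
  # per-element gradient magnitude bounded by 1/n
  g <- deepcount:::huber_grad(c(-30, 0.2, 4), c(0, 0, 0))
  expect_true(all(abs(g) <= 1 / 3 + 1e-12))
})

test_that("the regressor head follows the two-layer contract", {
  m <- build_regressor(backbone_spec("tiny"), regression_head_spec())
  f <- m$backbone$feature_width
  expect_equal(head_param_count(m), f * 512 + 512 + 512 + 1)
  mw <- build_regressor(backbone_spec("tiny-wide"), regression_head_spec(256))
  expect_equal(head_param_count(mw), 96 * 256 + 256 + 256 + 1)

  expect_error(backbone_spec("resnet18"), "supported backbones")
  expect_error(backbone_spec("tiny", pretrained = TRUE), "pretrained")
  expect_error(regression_head_spec(output_width = 2), "must be 1")

  secs <- deepcount:::param_sections(m)
  expect_setequal(names(secs), names(m$params))
  expect_true(all(secs %in% 1:3))
  expect_setequal(names(secs)[secs == 3], c("fc1.w", "fc1.b", "fc2.w", "fc2.b"))
})

test_that("prediction is deterministic, has batch arity, and starts at zero", {
  m <- build_regressor()
  ds <- tiny_dot_dataset(5, seed = 31, counts = 0:20)
  p1 <- predict_counts(m, ds)
  expect_length(p1, 5)
  expect_true(all(p1 == 0))  # zero-initialised final layer
  m2 <- withr::with_seed(1, {
    m$params <- lapply(m$params, function(p) p + stats::rnorm(length(p), sd = 0.05))
    m
  })
  p2 <- predict_counts(m2, ds)
  expect_identical(p2, predict_counts(m2, ds))
  expect_length(predict_counts(m2, ds$items[[1]]), 1)
  # squeeze-resize path for off-size inputs
  big <- matrix(runif(80 * 70), 80, 70)
  expect_length(predict_counts(m2, big), 1)
  expect_error(predict_counts(m2, "nope"), "must be")
})

test_that("backpropagation matches numeric finite differences", {
  m <- build_regressor(backbone_spec("tiny", input_size = c(16, 16)),
                       regression_head_spec(hidden_width = 8), seed = 2)
  # non-degenerate head
  m$params <- withr::with_seed(3, lapply(m$params, function(p)
    p + stats::rnorm(length(p), sd = 0.1)))
  x <- withr::with_seed(4, array(stats::rnorm(16 * 16 * 2), c(16, 16, 1, 2)))
  y <- c(3, 7)
  loss_at <- function(params) {
    mm <- m; mm$params <- params
    huber_loss(deepcount:::nn_forward(mm, x)$out, y)
  }
  fwd <- deepcount:::nn_forward(m, x, keep_cache = TRUE)
  grads <- deepcount:::nn_backward(m, fwd$cache,
                                   deepcount:::huber_grad(fwd$out, y))
  eps <- 1e-6
  withr::with_seed(5, {
    for (nm in c("conv1.w", "conv2.w", "conv3.b", "conv4.w", "fc1.w", "fc2.w", "fc2.b")) {
      for (k in sample(seq_along(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
        pp <- m$params; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- m$params; pm[[nm]][k] <- pm[[nm]][k] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_equal(grads[[nm]][k], num, tolerance = 1e-5,
                     info = sprintf("%s[%d]", nm, k))
      }
    }
  })
})

test_that("checkpoints round-trip with their manifest", {
  m <- build_regressor()
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "ckpt")
  save_regressor(m, stem, extra = list(epoch = 3L))
  back <- load_regressor(stem)
  expect_identical(back$params, m$params)
  man <- yaml::read_yaml(paste0(stem, ".yaml"))
  expect_equal(man$backbone, "tiny")
  expect_equal(man$epoch, 3L)
})
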