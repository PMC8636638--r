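test_that("the one-cycle schedule rises once to its peak and anneals below the start", {
  cyc <- one_cycle_spec()
  total <- 1000
  lrs <- one_cycle_lr(0:(total - 1), total, base_lr = 1e-2, cycle = cyc)
  warm <- ceiling(cyc$warmup_fraction * total)
  expect_equal(lrs[warm + 1], 1e-2)              # peak exactly at the boundary
  expect_lt(lrs[1], 1e-2)                        # starts strictly below
  expect_equal(which.max(lrs), warm + 1)
  expect_equal(sum(diff(sign(diff(lrs))) != 0), 1)  # unimodal
  expect_lt(lrs[total], lrs[1])
  expect_error(one_cycle_lr(0, 0, 1e-2), "positive")
})

test_that("phase specifications enforce ordering and freezing rules", {
  expect_error(phase_spec(5, c(1e-3, 1e-4, 1e-2)), "nondecreasing")
  expect_error(phase_spec(5, 1e-3, frozen_sections = 3), "never")
  p <- phase_spec(5, discriminative_lrs(1e-5, 1e-3))
  expect_equal(p$section_lrs, c(1e-5, 1e-4, 1e-3))
})

test_that("published protocol presets carry the original learning rates", {
  oto <- protocol_preset("otolith")
  expect_equal(oto$head_phase$section_lrs[3], 5e-2)
  expect_equal(oto$head_phase$epochs, 25L)
  expect_equal(oto$finetune_phase$section_lrs[c(1, 3)], c(9e-7, 9e-5))
  expect_equal(oto$batch_size, 84L)
  seal <- protocol_preset("seal")
  expect_equal(seal$head_phase$section_lrs[3], 3e-2)
  expect_equal(seal$finetune_phase$section_lrs[c(1, 3)], c(3e-4, 3e-2))
  expect_equal(seal$batch_size, 100L)
})

test_that("training honours freeze, zero-epoch and checkpoint contracts", {
  ds <- tiny_dot_dataset(24, seed = 51, counts = 0:10)
  tv <- train_val_split(ds, 0.75, seed = 1)
  m <- build_regressor(seed = 8)
  m <- set_normalization(m, tv$train)

  zero <- train_phase(m, tv$train, tv$validation, phase_spec(0, 1e-3))
  expect_identical(zero$model$params, m$params)
  expect_equal(nrow(zero$history), 0)

  cfg <- train_config(batch_size = 8, seed = 3)
  res <- train_phase(m, tv$train, tv$validation,
                     phase_spec(2, 1e-2, frozen_sections = 1:2), cfg)
  for (nm in deepcount:::section_params(m, 1))
    expect_identical(res$model$params[[nm]], m$params[[nm]], info = nm)
  for (nm in deepcount:::section_params(m, 2))
    expect_identical(res$model$params[[nm]], m$params[[nm]], info = nm)
  expect_false(identical(res$model$params[["fc1.w"]], m$params[["fc1.w"]]))

  # checkpoint = minimum validation loss over recorded epochs
  expect_equal(deepcount:::validation_loss(res$model, tv$validation),
               min(res$history$val_loss), tolerance = 1e-10)

  # identical seeds reproduce the loss history exactly
  res2 <- train_phase(m, tv$train, tv$validation,
                      phase_spec(2, 1e-2, frozen_sections = 1:2), cfg)
  expect_identical(res$history, res2$history)
})

test_that("a short full protocol reduces the training loss", {
  ds <- tiny_dot_dataset(80, seed = 52, counts = 0:12)
  tv <- train_val_split(ds, 0.8, seed = 2)
  train <- set_augmentation(tv$train, augmentation_policy())
  m <- build_regressor(seed = 9)
  m <- set_normalization(m, train)
  res <- train_phase(m, train, tv$validation,
                     phase_spec(6, discriminative_lrs(5e-4, 3e-3)),
                     train_config(batch_size = 16, seed = 4))
  expect_lt(tail(res$history$train_loss, 1), res$history$train_loss[1])
  # protocol with both phases at 0 epochs is the identity
  same <- run_protocol(m, train, tv$validation,
                       phase_spec(0, 1e-3), phase_spec(0, 1e-3))
  expect_identical(same$params, m$params)
})
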