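test_that("discrepancy records sort by residual with id tie-breaks", {
  rec <- discrepancy_records(c("d", "a", "c", "b"),
                             noisy_label = c(5L, 5L, 8L, 1L),
                             predicted = c(5, 5, 7, -6))
  expect_equal(rec$residual, c(0, 0, -1, -7))
  expect_equal(rec$id, c("a", "d", "c", "b"))  # ties broken by ascending id

  m <- build_regressor()  # zero head: predicts 0, residual = -label
  pool <- tiny_dot_dataset(20, seed = 61, counts = 0:15)
  rk <- rank_discrepancies(m, pool)
  expect_equal(nrow(rk), 20)
  ref <- data.frame(id = dataset_ids(pool), residual = -labels(pool))
  ref <- ref[order(-ref$residual, ref$id), ]
  expect_equal(rk$id, ref$id)
  expect_equal(rk$residual, ref$residual)
})

test_that("tail selection picks the extremes and replaces unidentifiable images", {
  pool <- label_only_dataset(c(0L, 3L, 9L, 7L), prefix = "p")
  # residuals: +5, +2, -1, -7 for ids p-00001..p-00004
  rec <- discrepancy_records(dataset_ids(pool), labels(pool),
                             predicted = c(5, 5, 8, 0))
  expect_equal(rec$residual[c(1, nrow(rec))], c(5, -7))
  cfg <- refinement_config(k_over = 1, k_under = 1)
  sel <- select_refinement_set(pool, rec, cfg)
  rep <- attr(sel, "report")
  expect_setequal(rep$residual, c(5, -7))
  expect_equal(sort(rep$tail), c("over", "under"))
  expect_true(all(labels(sel) == true_labels(sel)))

  # top over-estimated image unidentifiable -> next in the same tail
  pool2 <- pool
  pool2$items[[1]]$flags$unidentifiable <- TRUE
  sel2 <- select_refinement_set(pool2, rec, cfg)
  rep2 <- attr(sel2, "report")
  expect_setequal(rep2$residual, c(2, -7))
  expect_true(rep2$replaced_flag[rep2$tail == "over"])
  expect_equal(attr(sel2, "n_discarded"), 1L)

  # both tails wanting everything -> the whole identifiable pool, no duplicates
  all_sel <- select_refinement_set(pool, rec, refinement_config(3, 3))
  expect_setequal(attr(all_sel, "report")$id, dataset_ids(pool))
  expect_equal(anyDuplicated(dataset_ids(all_sel)), 0L)

  # exhaustion by unidentifiable images is an explanatory failure
  pool3 <- pool
  for (i in 1:3) pool3$items[[i]]$flags$unidentifiable <- TRUE
  expect_error(select_refinement_set(pool3, rec, refinement_config(2, 0)),
               "over tail")
})

test_that("selection equals brute-force enumeration on random pools", {
  withr::with_seed(62, {
    for (i in 1:60) {
      n <- sample(20:120, 1)
      labs <- sample(0:40, n, replace = TRUE)
      flagged <- runif(n) < 0.15
      pool <- label_only_dataset(labs, prefix = sprintf("q%03d", i),
                                 unidentifiable = flagged)
      rec <- discrepancy_records(dataset_ids(pool), labs,
                                 predicted = labs + rnorm(n, sd = 6))
      k_over <- sample(0:8, 1); k_under <- sample(0:8, 1)
      ref <- brute_force_selection(rec, dataset_ids(pool)[flagged], k_over, k_under)
      got <- try(select_refinement_set(pool, rec,
                                       refinement_config(k_over, k_under)),
                 silent = TRUE)
      if (length(ref$over) < k_over || length(ref$under) < k_under) {
        expect_s3_class(got, "try-error")
        next
      }
      repgot <- attr(got, "report")
      expect_identical(repgot$id[repgot$tail == "over"], ref$over)
      expect_identical(repgot$id[repgot$tail == "under"], ref$under)
    }
  })
})

test_that("refine re-splits with the floor rule and rejects id collisions", {
  s1 <- label_only_dataset(rep(2L, 787), prefix = "s1")
  s2 <- label_only_dataset(rep(9L, 100), prefix = "s2")
  merged <- concat_datasets(s1, s2)
  tv <- train_val_split(merged, 0.8, seed = 1)
  expect_equal(length(tv$train), 709)
  expect_equal(length(tv$validation), 178)

  m <- build_regressor()
  expect_error(refine(m, s1, s1, refinement_config(1, 1)), "share")

  # empty subset2 and zero fine-tune epochs leave the model unchanged
  out <- refine(m, s1, count_dataset(list()),
                refinement_config(0, 0, finetune_phase = phase_spec(0, 1e-3)))
  expect_identical(out$params, m$params)
})
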