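#' End-to-end experiment configuration
#'
#' One object (or YAML file) describing a full synthetic counting experiment:
#' generator, split design, model, training protocol and optional refinement.
#' A single global seed deterministically derives every stage seed.
#'
#' @param scenario `"dot"` or `"ring"`.
#' @param generator a [dot_scene_spec()] or [ring_image_spec()]; defaults per
#'   scenario.
#' @param n_images total images generated before splitting.
#' @param count_distribution optional named weights (see [make_dataset()]).
#' @param split a [split_spec()] (bins, per-bin test draw, train fraction).
#' @param backbone,head model specifications.
#' @param protocol list with `head_phase` and `finetune_phase` (see
#'   [desk_protocol()]).
#' @param train a [train_config()].
#' @param augmentation an [augmentation_policy()] for the training set.
#' @param refinement optional list for [run_refinement_experiment()]:
#'   `config` (a [refinement_config()]), `noise` (a [label_noise_model()]),
#'   `n_pool` (noisy-pool size) and `clean_cap_fraction` (upper label cap of
#'   the clean subset as a fraction of the count range).
#' @param seed global integer seed.
#' @param out_dir optional artifact directory.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("dot", "ring"),
                              generator = NULL,
                              n_images = 870,
                              count_distribution = NULL,
                              split = split_spec(n_bins = 8, per_bin = 15),
                              backbone = backbone_spec("tiny"),
                              head = regression_head_spec(),
                              protocol = desk_protocol(),
                              train = train_config(),
                              augmentation = augmentation_policy(),
                              refinement = NULL,
                              seed = 1, out_dir = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(generator))
    generator <- if (scenario == "dot") dot_scene_spec() else ring_image_spec()
  structure(list(scenario = scenario, generator = generator,
                 n_images = as.integer(n_images),
                 count_distribution = count_distribution,
                 split = split, backbone = backbone, head = head,
                 protocol = protocol, train = train,
                 augmentation = augmentation, refinement = refinement,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

prepare_splits <- function(config) {
  dataset <- make_dataset(config$generator, config$n_images,
                          config$count_distribution,
                          seed = derive_seed(config$seed, 100))
  dataset <- assign_bins(dataset, config$split$n_bins)
  sp <- config$split
  sp$seed <- derive_seed(config$seed, 200)
  parts <- stratified_test_split(dataset, sp)
  tv <- train_val_split(parts$remainder, sp$train_fraction,
                        seed = derive_seed(config$seed, 300))
  train <- set_augmentation(tv$train, config$augmentation)
  list(test = parts$test, train = train, validation = tv$validation)
}

write_experiment_artifacts <- function(dir, splits, model, report, preds) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(splits))
    write_id_list(splits[[nm]], file.path(dir, paste0(nm, "-ids.txt")))
  hist <- attr(model, "history")
  if (!is.null(hist))
    utils::write.csv(do.call(rbind, c(hist, list(make.row.names = FALSE))),
                     file.path(dir, "history.csv"), row.names = FALSE)
  vb <- if (!is.null(hist) && nrow(hist$finetune)) min(hist$finetune$val_loss) else NA
  save_regressor(model, file.path(dir, "model"), extra = list(val_best = vb))
  write_metric_report(report, file.path(dir, "metrics"))
  export_scatter(labels(splits$test), preds, file.path(dir, "scatter.csv"))
}

#' Run a complete counting experiment
#'
#' Generates a synthetic dataset, builds the stratified binned test set and
#' the train/validation split, trains the regressor with the two-phase
#' protocol, and evaluates on the test set. With an `out_dir`, split id
#' lists, training history, the checkpoint, the metric report, scatter data
#' and CAM overlays for a handful of test images are written there.
#'
#' @param config an [experiment_config()].
#' @return list with `report` (a [compute_metrics()] result on the test
#'   set), `model`, `splits`, and `predictions`.
#' @export
run_counting_experiment <- function(config) {
  assert_that(inherits(config, "experiment_config"),
              "`config` must be an experiment_config")
  splits <- prepare_splits(config)
  model <- build_regressor(config$backbone, config$head,
                           seed = derive_seed(config$seed, 400))
  model <- set_normalization(model, splits$train)
  tc <- config$train
  tc$seed <- derive_seed(config$seed, 500)
  model <- run_protocol(model, splits$train, splits$validation,
                        config$protocol$head_phase, config$protocol$finetune_phase,
                        tc)
  preds <- predict_counts(model, splits$test)
  report <- compute_metrics(labels(splits$test), preds)
  if (!is.null(config$out_dir)) {
    write_experiment_artifacts(config$out_dir, splits, model, report, preds)
    cams <- splits$test[seq_len(min(6, length(splits$test)))]
    write_cam_overlays(model, cams, file.path(config$out_dir, "cam"))
  }
  list(report = report, model = model, splits = splits, predictions = preds)
}

#' Run the two-step refinement experiment
#'
#' Synthetic replication of the noisy-label study design: the clean training
#' subset is biased towards low counts (a hard cap at `clean_cap_fraction` of
#' the count range), while a larger pool spans the full range but carries
#' undercount label noise. A step-1 model is trained on the clean subset and
#' evaluated; the pool is then ranked by prediction discrepancy, the extreme
#' tails are oracle-relabelled (with discard-and-replace for unidentifiable
#' images), and the model is fine-tuned on the extended set. Both steps are
#' evaluated on the same stratified test set.
#'
#' @param config an [experiment_config()] whose `refinement` entry is set.
#' @return list with `step1`, `step2` (metric reports on the shared test
#'   set), `upper_rmse` (step-1/step-2 RMSE restricted to test labels above
#'   the clean cap), `selection` (the selection report), `model_step1`,
#'   `model_step2`, and `test`.
#' @export
run_refinement_experiment <- function(config) {
  assert_that(!is.null(config$refinement),
              "`config$refinement` must be set for a refinement experiment")
  ref <- config$refinement
  gen <- config$generator
  rng <- gen$count_range
  cap <- rng[1] + floor((ref$clean_cap_fraction %||% 0.4) * (rng[2] - rng[1]))

  # clean, low-count-biased subset 1
  w_clean <- skewed_count_weights(c(rng[1], cap), rate = 2)
  clean <- make_dataset(gen, config$n_images, w_clean,
                        seed = derive_seed(config$seed, 110),
                        id_prefix = "clean")
  tv <- train_val_split(clean, config$split$train_fraction,
                        seed = derive_seed(config$seed, 310))
  train1 <- set_augmentation(tv$train, config$augmentation)

  # noisy pool spanning the full count range
  pool <- make_dataset(gen, ref$n_pool %||% 500,
                       skewed_count_weights(rng, rate = 1.5),
                       seed = derive_seed(config$seed, 120),
                       id_prefix = "pool")
  pool <- corrupt_labels(pool, ref$noise, seed = derive_seed(config$seed, 130))

  # stratified test set over the full range, from clean images
  test_pool <- make_dataset(gen, config$split$n_bins * config$split$per_bin * 3,
                            stats::setNames(rep(1, rng[2] - rng[1] + 1),
                                            rng[1]:rng[2]),
                            seed = derive_seed(config$seed, 140),
                            id_prefix = "test")
  sp <- config$split
  sp$seed <- derive_seed(config$seed, 240)
  test <- stratified_test_split(assign_bins(test_pool, sp$n_bins), sp)$test

  model <- build_regressor(config$backbone, config$head,
                           seed = derive_seed(config$seed, 400))
  model <- set_normalization(model, train1)
  tc <- config$train
  tc$seed <- derive_seed(config$seed, 500)
  model1 <- run_protocol(model, train1, tv$validation,
                         config$protocol$head_phase,
                         config$protocol$finetune_phase, tc)
  preds1 <- predict_counts(model1, test)
  report1 <- compute_metrics(labels(test), preds1)

  records <- rank_discrepancies(model1, pool)
  rcfg <- ref$config
  rcfg$train$seed <- derive_seed(config$seed, 600)
  subset2 <- select_refinement_set(pool, records, rcfg)
  model2 <- refine(model1, tv$train, subset2, rcfg)
  preds2 <- predict_counts(model2, test)
  report2 <- compute_metrics(labels(test), preds2)

  upper <- labels(test) > cap
  upper_rmse <- c(step1 = sqrt(mean((preds1[upper] - labels(test)[upper])^2)),
                  step2 = sqrt(mean((preds2[upper] - labels(test)[upper])^2)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(attr(subset2, "report"),
                     file.path(config$out_dir, "selection.csv"), row.names = FALSE)
    write_metric_report(report1, file.path(config$out_dir, "metrics-step1"))
    write_metric_report(report2, file.path(config$out_dir, "metrics-step2"))
    export_scatter(labels(test), preds2, file.path(config$out_dir, "scatter-step2.csv"))
  }
  list(step1 = report1, step2 = report2, upper_rmse = upper_rmse,
       selection = attr(subset2, "report"),
       n_discarded = attr(subset2, "n_discarded"),
       model_step1 = model1, model_step2 = model2, test = test)
}

#' Read an experiment configuration from YAML
#'
#' Thin front door for the command-line interface: scalar fields map directly
#' onto [experiment_config()] arguments; generator/split/protocol blocks are
#' passed to the corresponding constructors.
#'
#' @param path YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- y$scenario %||% "dot"
  gen <- if (!is.null(y$generator))
    do.call(if (scenario == "dot") dot_scene_spec else ring_image_spec,
            lapply(y$generator, function(v) if (is.list(v)) unlist(v) else v))
  split <- if (!is.null(y$split)) do.call(split_spec, y$split)
  else split_spec(8, 15)
  protocol <- if (!is.null(y$protocol)) do.call(desk_protocol, y$protocol)
  else desk_protocol()
  refinement <- if (!is.null(y$refinement)) {
    list(config = do.call(refinement_config,
                          y$refinement$config %||% list()),
         noise = do.call(label_noise_model, y$refinement$noise %||% list()),
         n_pool = y$refinement$n_pool,
         clean_cap_fraction = y$refinement$clean_cap_fraction)
  }
  experiment_config(scenario = scenario, generator = gen,
                    n_images = y$n_images %||% 870,
                    split = split,
                    backbone = backbone_spec(y$backbone %||% "tiny"),
                    protocol = protocol,
                    train = train_config(batch_size = y$batch_size %||% 64,
                                         seed = y$seed %||% 1),
                    refinement = refinement,
                    seed = y$seed %||% 1, out_dir = y$out_dir)
}
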