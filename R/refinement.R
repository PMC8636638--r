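#' Refinement configuration
#'
#' Controls the two-step noisy-label refinement: how many images are taken
#' from each discrepancy tail, and the fine-tuning phase applied after the
#' selected images have been relabelled. Replacement of unidentifiable images
#' stays within the same tail (the next most poorly predicted image in the
#' same direction), preserving the over/under balance of the selection.
#'
#' @param k_over images taken from the most over-estimated tail.
#' @param k_under images taken from the most under-estimated tail.
#' @param finetune_phase a [phase_spec()] for the post-relabelling fine-tune;
#'   all sections unfrozen, discriminative learning rates.
#' @param train a [train_config()] for the fine-tune.
#' @param train_fraction train share of the merged subset re-split.
#' @return an object of class `refinement_config`.
#' @export
refinement_config <- function(k_over = 50, k_under = 50,
                              finetune_phase = phase_spec(
                                50, discriminative_lrs(1e-5, 1e-3)),
                              train = train_config(),
                              train_fraction = 0.8) {
  assert_that(k_over >= 0 && k_under >= 0, "`k_over` and `k_under` must be >= 0")
  structure(list(k_over = as.integer(k_over), k_under = as.integer(k_under),
                 finetune_phase = finetune_phase, train = train,
                 train_fraction = train_fraction),
            class = "refinement_config")
}

#' Construct discrepancy records
#'
#' @param id character image ids.
#' @param noisy_label integer labels as stored in the (noisy) pool.
#' @param predicted raw model predictions.
#' @return a `discrepancy_records` data frame sorted by signed residual
#'   (`predicted - noisy_label`) descending, ties broken by ascending id.
#' @export
discrepancy_records <- function(id, noisy_label, predicted) {
  df <- data.frame(id = as.character(id), noisy_label = as.integer(noisy_label),
                   predicted = as.numeric(predicted), stringsAsFactors = FALSE)
  df$residual <- df$predicted - df$noisy_label
  df <- df[order(-df$residual, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("discrepancy_records", "data.frame")
  df
}

#' Rank a noisy pool by prediction discrepancy
#'
#' Predicts raw (unrounded) counts for every pool image and computes the
#' signed residual against the stored noisy label. The result is sorted with
#' the most over-estimated images first and the most under-estimated last;
#' ties are broken by ascending id so the ordering is deterministic.
#'
#' @param model a trained [count_regressor()].
#' @param noisy_pool a nonempty [count_dataset()] with noisy labels.
#' @return a [discrepancy_records()] data frame.
#' @export
rank_discrepancies <- function(model, noisy_pool) {
  assert_that(length(noisy_pool) >= 1, "`noisy_pool` must be nonempty")
  discrepancy_records(dataset_ids(noisy_pool), labels(noisy_pool),
                      predict_counts(model, noisy_pool))
}

#' Select and relabel the refinement set
#'
#' Walks the discrepancy ranking from both ends: the `k_over` most
#' over-estimated and `k_under` most under-estimated images are relabelled by
#' the oracle. Images the oracle cannot recount (unidentifiable) are
#' discarded and replaced by the next most poorly predicted image in the same
#' tail. Selected images carry the oracle label and lose their noisy flag.
#'
#' @param pool the [count_dataset()] the records were ranked from.
#' @param records a [discrepancy_records()] data frame for `pool`.
#' @param config a [refinement_config()].
#' @param oracle function mapping a [labelled_image()] to an integer count or
#'   `NA_integer_` (unidentifiable); defaults to [oracle_relabel()].
#' @return a [count_dataset()] of the relabelled selection. The selection
#'   report (columns `id`, `noisy_label`, `predicted`, `residual`, `tail`,
#'   `replaced_flag`, `oracle_label`) is attached as attribute `"report"`, and
#'   the number of discarded images as `"n_discarded"`.
#' @export
select_refinement_set <- function(pool, records, config, oracle = oracle_relabel) {
  assert_that(inherits(records, "discrepancy_records"),
              "`records` must come from rank_discrepancies()")
  by_id <- stats::setNames(seq_along(pool$items), dataset_ids(pool))
  n <- nrow(records)
  taken <- logical(n)
  discarded <- 0L

  walk_tail <- function(order_idx, k, tail_name) {
    sel <- integer(0); oracle_lab <- integer(0); replaced <- logical(0)
    rank_in_tail <- 0L
    for (i in order_idx) {
      if (length(sel) >= k) break
      if (taken[i]) next
      rank_in_tail <- rank_in_tail + 1L
      img <- pool$items[[by_id[[records$id[i]]]]]
      lab <- oracle(img)
      if (is.na(lab)) { discarded <<- discarded + 1L; next }
      taken[i] <<- TRUE
      sel <- c(sel, i)
      oracle_lab <- c(oracle_lab, lab)
      replaced <- c(replaced, rank_in_tail > k)
    }
    if (length(sel) < k && sum(!taken) > 0)
      stop(sprintf("pool exhausted while filling the %s tail: %d of %d slots unfilled",
                   tail_name, k - length(sel), k), call. = FALSE)
    data.frame(i = sel, oracle_label = oracle_lab, replaced_flag = replaced,
               tail = if (length(sel)) tail_name else character(0))
  }
  over <- walk_tail(seq_len(n), config$k_over, "over")
  under <- walk_tail(rev(seq_len(n)), config$k_under, "under")
  chosen <- rbind(over, under)

  items <- lapply(seq_len(nrow(chosen)), function(j) {
    rec <- records[chosen$i[j], ]
    img <- pool$items[[by_id[[rec$id]]]]
    img$label <- chosen$oracle_label[j]
    img$flags$noisy <- FALSE
    img
  })
  out <- count_dataset(items)
  report <- data.frame(id = records$id[chosen$i],
                       noisy_label = records$noisy_label[chosen$i],
                       predicted = records$predicted[chosen$i],
                       residual = records$residual[chosen$i],
                       tail = chosen$tail,
                       replaced_flag = chosen$replaced_flag,
                       oracle_label = chosen$oracle_label,
                       stringsAsFactors = FALSE)
  attr(out, "report") <- report
  attr(out, "n_discarded") <- discarded
  out
}

#' Fine-tune on the extended training set
#'
#' Merges the clean subset with the relabelled refinement subset, re-splits
#' the union into training and validation sets, and fine-tunes the whole
#' network (all sections unfrozen) with best-validation-epoch checkpointing.
#'
#' @param model the step-1 [count_regressor()].
#' @param subset1 the clean training subset.
#' @param subset2 the oracle-relabelled refinement subset (ids must be
#'   disjoint from `subset1`).
#' @param config a [refinement_config()].
#' @return the step-2 model; the fine-tune history is attached as attribute
#'   `"history"`.
#' @export
refine <- function(model, subset1, subset2, config = refinement_config()) {
  dup <- intersect(dataset_ids(subset1), dataset_ids(subset2))
  if (length(dup))
    stop(sprintf("subsets share %d id(s), e.g. '%s'", length(dup), dup[1]),
         call. = FALSE)
  if (config$finetune_phase$epochs == 0 && length(subset2) == 0) return(model)
  merged <- concat_datasets(subset1, subset2)
  merged$augmentation <- subset1$augmentation
  parts <- train_val_split(merged, config$train_fraction,
                           seed = derive_seed(config$train$seed, 31))
  phase <- config$finetune_phase
  phase$frozen_sections <- integer()
  res <- train_phase(model, parts$train, parts$validation, phase, config$train)
  out <- res$model
  attr(out, "history") <- res$history
  out
}
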