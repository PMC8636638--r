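#' Split specification for stratified test-set construction
#'
#' @param n_bins number of equal-width label bins.
#' @param per_bin number of images drawn from each bin for the test set.
#' @param train_fraction fraction of the remainder used for training (the
#'   rest becomes the validation set).
#' @param seed integer seed for all random draws.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(n_bins, per_bin, train_fraction = 0.8, seed = 1) {
  assert_that(n_bins >= 1, "`n_bins` must be >= 1")
  assert_that(per_bin >= 0, "`per_bin` must be >= 0")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "`train_fraction` must lie in (0, 1)")
  structure(list(n_bins = as.integer(n_bins), per_bin = as.integer(per_bin),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

bin_indices <- function(lab, n_bins) {
  lo <- min(lab); hi <- max(lab)
  if (lo == hi && n_bins > 1)
    stop(sprintf("all labels equal %d: cannot form %d label bins", lo, n_bins),
         call. = FALSE)
  if (n_bins == 1) return(rep(0L, length(lab)))
  width <- (hi - lo) / n_bins
  pmin(as.integer(floor((lab - lo) / width)), n_bins - 1L)
}

#' Assign equal-width label bins
#'
#' Bins span `[min(label), max(label)]` with equal width; the maximum label is
#' included in the last bin (closed upper edge), so every item receives
#' exactly one bin index in `[0, n_bins)`.
#'
#' @param dataset a [count_dataset()].
#' @param n_bins number of bins.
#' @return the dataset with `label_bins` filled in.
#' @export
assign_bins <- function(dataset, n_bins) {
  assert_that(length(dataset) >= 1, "`dataset` must be nonempty")
  dataset$label_bins <- bin_indices(labels(dataset), n_bins)
  dataset
}

#' Stratified test split over label bins
#'
#' Draws `per_bin` images uniformly without replacement from every label bin,
#' so rare high counts are represented in the test set in proportion to the
#' bin design rather than their abundance. The result is an exact partition:
#' `test` and `remainder` are disjoint and their union is the input.
#'
#' @param dataset a [count_dataset()]; bins are assigned with
#'   [assign_bins()] (using `spec$n_bins`) if not already present.
#' @param spec a [split_spec()].
#' @return list with elements `test` and `remainder`, both [count_dataset()]s.
#' @export
stratified_test_split <- function(dataset, spec) {
  assert_that(inherits(spec, "split_spec"), "`spec` must be a split_spec")
  if (is.null(dataset$label_bins) || max(dataset$label_bins) >= spec$n_bins)
    dataset <- assign_bins(dataset, spec$n_bins)
  bins <- dataset$label_bins
  take <- integer(0)
  withr::with_seed(derive_seed(spec$seed, 11), {
    for (b in 0:(spec$n_bins - 1L)) {
      idx <- which(bins == b)
      if (length(idx) < spec$per_bin)
        stop(sprintf("bin %d holds only %d images but per_bin = %d",
                     b, length(idx), spec$per_bin), call. = FALSE)
      if (spec$per_bin > 0)
        take <- c(take, idx[sample.int(length(idx), spec$per_bin)])
    }
  })
  take <- sort(take)
  keep <- setdiff(seq_along(bins), take)
  list(test = dataset[take], remainder = dataset[keep])
}

#' Random train/validation split
#'
#' The training set holds `floor(train_fraction * n)` images drawn uniformly
#' without replacement; the remainder is the validation set. Item order
#' within each part follows the input order.
#'
#' @param dataset a [count_dataset()] with at least two items.
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `validation`.
#' @export
train_val_split <- function(dataset, train_fraction = 0.8, seed = 1) {
  n <- length(dataset)
  assert_that(n >= 2, "`dataset` must hold at least two items")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "`train_fraction` must lie in (0, 1)")
  n_train <- floor(train_fraction * n)
  idx <- withr::with_seed(derive_seed(seed, 12),
                          sort(sample.int(n, n_train)))
  list(train = dataset[idx], validation = dataset[setdiff(seq_len(n), idx)])
}

#' Write split membership as an id list
#'
#' @param dataset a [count_dataset()].
#' @param path output file; one id per line, UTF-8.
#' @return `path`, invisibly.
#' @export
write_id_list <- function(dataset, path) {
  writeLines(dataset_ids(dataset), path, useBytes = TRUE)
  invisible(path)
}
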