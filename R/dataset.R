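#' Labelled image
#'
#' The elementary record of the package: a raster intensity grid together with
#' an image-level integer count label and bookkeeping metadata. Pixels are a
#' numeric matrix in `[0, 1]` (grey) or an `H x W x 3` array (RGB); `pixels`
#' may be `NULL` for label-only records used in split arithmetic.
#'
#' @param pixels numeric matrix (or 3-d array), intensities in `[0, 1]`, or `NULL`.
#' @param label nonnegative integer count associated with the whole image.
#' @param id stable character identifier, unique within a dataset.
#' @param true_label the verified count when `label` may be noisy; defaults to
#'   `label`.
#' @param noisy logical: is `label` suspected to under-report the true count?
#' @param unidentifiable logical: are the objects too small/blurred for a human
#'   recount (such images are discarded during refinement)?
#' @param meta free-form list of generator metadata (object geometry, scene
#'   scale, lighting), used by mask extraction and the relabelling oracle.
#' @return an object of class `labelled_image`.
#' @seealso [count_dataset()], [oracle_relabel()]
#' @export
labelled_image <- function(pixels, label, id,
                           true_label = label,
                           noisy = FALSE, unidentifiable = FALSE,
                           meta = list()) {
  assert_that(is.numeric(label) && length(label) == 1 && label >= 0,
              "`label` must be a single nonnegative count")
  assert_that(is.character(id) && length(id) == 1 && nzchar(id),
              "`id` must be a non-empty string")
  if (!is.null(pixels)) {
    assert_that(is.numeric(pixels) && length(dim(pixels)) %in% c(2L, 3L),
                "`pixels` must be a numeric matrix or 3-d array, or NULL")
  }
  structure(list(pixels = pixels,
                 label = as.integer(round(label)),
                 true_label = if (is.null(true_label)) NULL else as.integer(round(true_label)),
                 flags = list(noisy = isTRUE(noisy),
                              unidentifiable = isTRUE(unidentifiable)),
                 id = id,
                 meta = meta),
            class = "labelled_image")
}

#' @export
print.labelled_image <- function(x, ...) {
  d <- if (is.null(x$pixels)) "label-only" else paste(dim(x$pixels), collapse = "x")
  cat(sprintf("<labelled_image %s> label=%d%s [%s]%s%s\n", x$id, x$label,
              if (!is.null(x$true_label) && x$true_label != x$label)
                sprintf(" (true %d)", x$true_label) else "",
              d,
              if (x$flags$noisy) " noisy" else "",
              if (x$flags$unidentifiable) " unidentifiable" else ""))
  invisible(x)
}

#' Ordered collection of labelled images
#'
#' @param items list of [labelled_image()] objects with unique ids.
#' @param label_bins optional integer vector of per-item bin indices in
#'   `[0, n_bins)`, as produced by [assign_bins()].
#' @return an object of class `count_dataset`.
#' @export
count_dataset <- function(items, label_bins = NULL) {
  assert_that(is.list(items), "`items` must be a list of labelled_image objects")
  ok <- vapply(items, inherits, logical(1), what = "labelled_image")
  assert_that(all(ok), "every item must be a labelled_image")
  ids <- vapply(items, `[[`, character(1), "id")
  assert_that(!anyDuplicated(ids), "item ids must be unique within a dataset")
  if (!is.null(label_bins))
    assert_that(length(label_bins) == length(items),
                "`label_bins` must have one entry per item")
  structure(list(items = items, label_bins = label_bins,
                 augmentation = NULL),
            class = "count_dataset")
}

#' @export
length.count_dataset <- function(x) length(x$items)

#' @export
`[.count_dataset` <- function(x, i) {
  out <- count_dataset(x$items[i],
                       label_bins = if (!is.null(x$label_bins)) x$label_bins[i])
  out$augmentation <- x$augmentation
  out
}

#' @export
print.count_dataset <- function(x, ...) {
  l <- labels(x)
  cat(sprintf("<count_dataset> %d images, labels %d..%d (mean %.2f)%s%s\n",
              length(x), min(l), max(l), mean(l),
              if (!is.null(x$label_bins))
                sprintf(", %d bins", length(unique(x$label_bins))) else "",
              if (!is.null(x$augmentation)) ", augmented" else ""))
  invisible(x)
}

#' @export
labels.count_dataset <- function(object, ...) {
  vapply(object$items, `[[`, integer(1), "label")
}

#' Item identifiers of a dataset
#' @param dataset a [count_dataset()].
#' @return character vector of ids in item order.
#' @export
dataset_ids <- function(dataset) {
  vapply(dataset$items, `[[`, character(1), "id")
}

#' True (verified) labels of a dataset
#' @param dataset a [count_dataset()].
#' @return integer vector; `NA` where no verified label is recorded.
#' @export
true_labels <- function(dataset) {
  vapply(dataset$items, function(it) it$true_label %||% NA_integer_, integer(1))
}

#' Concatenate datasets
#'
#' @param dataset,... datasets to concatenate; ids must remain unique.
#' @return a [count_dataset()] with the items of all arguments in order.
#' @export
concat_datasets <- function(dataset, ...) {
  rest <- list(...)
  items <- c(dataset$items, unlist(lapply(rest, `[[`, "items"), recursive = FALSE))
  count_dataset(items)
}

#' Label-distribution summary of a dataset
#'
#' @param dataset a [count_dataset()].
#' @return data frame with one row per observed label: `label`, `n`, `frequency`.
#' @export
label_distribution <- function(dataset) {
  l <- labels(dataset)
  tab <- table(l)
  data.frame(label = as.integer(names(tab)), n = as.integer(tab),
             frequency = as.numeric(tab) / length(l))
}

#' Attach an augmentation policy to a dataset
#'
#' Training consumes the attached policy; validation and test sets are left
#' without one so that evaluation always sees un-augmented pixels.
#'
#' @param dataset a [count_dataset()].
#' @param policy an [augmentation_policy()] or `NULL` to detach.
#' @return the dataset with the policy attached.
#' @export
set_augmentation <- function(dataset, policy) {
  if (!is.null(policy))
    assert_that(inherits(policy, "augmentation_policy"),
                "`policy` must be an augmentation_policy")
  dataset$augmentation <- policy
  dataset
}

#' Write a dataset to disk
#'
#' Writes 8-bit PNG images plus the label manifest
#' `labels.csv` (columns `image_path,count,true_count,unidentifiable,noisy`)
#' and a YAML summary `manifest.yaml`.
#'
#' @param dataset a [count_dataset()] whose items carry pixels.
#' @param dir output directory, created if missing.
#' @param write_images write the PNG files (label manifest is always written).
#' @return `dir`, invisibly.
#' @export
write_count_dataset <- function(dataset, dir, write_images = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- dataset_ids(dataset)
  paths <- file.path("images", paste0(ids, ".png"))
  if (write_images) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    for (i in seq_along(dataset$items)) {
      px <- dataset$items[[i]]$pixels
      assert_that(!is.null(px), "cannot write a label-only dataset as images")
      png::writePNG(clamp01(px), file.path(dir, paths[i]))
    }
  }
  man <- data.frame(image_path = paths,
                    count = labels(dataset),
                    true_count = true_labels(dataset),
                    unidentifiable = vapply(dataset$items, function(it)
                      it$flags$unidentifiable, logical(1)),
                    noisy = vapply(dataset$items, function(it)
                      it$flags$noisy, logical(1)))
  utils::write.csv(man, file.path(dir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(list(n_images = length(dataset),
                        label_min = min(labels(dataset)),
                        label_max = max(labels(dataset)),
                        n_noisy = sum(man$noisy),
                        n_unidentifiable = sum(man$unidentifiable)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_count_dataset()]
#'
#' @param dir directory containing `labels.csv` and an `images/` folder.
#' @return a [count_dataset()].
#' @export
read_count_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  items <- lapply(seq_len(nrow(man)), function(i) {
    p <- file.path(dir, man$image_path[i])
    px <- if (file.exists(p)) {
      a <- png::readPNG(p)
      if (length(dim(a)) == 3 && dim(a)[3] == 1) a <- a[, , 1]
      a
    }
    labelled_image(px, man$count[i],
                   id = sub("\\.png$", "", basename(man$image_path[i])),
                   true_label = if (is.na(man$true_count[i])) NULL else man$true_count[i],
                   noisy = man$noisy[i], unidentifiable = man$unidentifiable[i])
  })
  count_dataset(items)
}
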