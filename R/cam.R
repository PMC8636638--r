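#' Class-activation heatmap for the regression output
#'
#' Gradient-weighted CAM adapted to a scalar regression head: channel weights
#' are the spatially averaged gradients of the predicted count with respect
#' to the last convolutional block's activations, the weighted activation sum
#' is rectified (keeping only regions that raise the count), min-max
#' normalised to `[0, 1]`, and bilinearly upsampled to the input size.
#' Because the head sits on global average pooling, the gradient is constant
#' over space and the channel weights have a closed form through the two
#' fully-connected layers. A constant raw map (e.g. zero gradients through a
#' dead head) yields the all-zero heatmap by convention; any non-constant map
#' attains both 0 and 1.
#'
#' @param model a trained [count_regressor()].
#' @param image a [labelled_image()] or numeric matrix at (or squeezed to)
#'   the model input size.
#' @return an object of class `heat_map`: list with `values` (matrix in
#'   `[0, 1]` of the input spatial size) and `image_id`.
#' @export
compute_cam <- function(model, image) {
  id <- if (inherits(image, "labelled_image")) image$id else "image"
  x <- assemble_batch(model, list(image))
  fwd <- nn_forward(model, x, keep_cache = TRUE)
  cache <- fwd$cache
  # d(out)/d(GAP features): back through fc2 and the fc1 ReLU
  dh1 <- as.numeric(t(model$params[["fc2.w"]])) * as.numeric(cache$h1_mask)
  w_ch <- as.numeric(t(model$params[["fc1.w"]]) %*% dh1)   # length F
  acts <- cache$last_act[, , , 1, drop = FALSE]
  d <- dim(acts)
  raw <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) raw <- raw + w_ch[c] * acts[, , c, 1]
  raw[raw < 0] <- 0
  hw <- model$backbone$input_size
  up <- squeeze_resize(raw, hw[1], hw[2])
  rng <- range(up)
  values <- if (rng[2] > rng[1]) (up - rng[1]) / (rng[2] - rng[1])
  else matrix(0, hw[1], hw[2])
  structure(list(values = clamp01(values), image_id = id), class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map %s> %dx%d, range [%.2f, %.2f]\n", x$image_id,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

heat_colors <- function(v) {
  # dark blue -> red -> yellow ramp, vectorised over a [0,1] matrix
  r <- clamp01(1.5 * v)
  g <- clamp01(2 * v - 1)
  b <- clamp01(1 - 2 * v)
  list(r = r, g = g, b = b)
}

#' Write an image/heatmap overlay
#'
#' Produces a side-by-side PNG: the greyscale input on the left and the
#' colour-mapped heatmap alpha-blended over it on the right.
#'
#' @param image a [labelled_image()] (or matrix) at the heatmap's size.
#' @param heatmap a [compute_cam()] result.
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap on the right panel.
#' @return `path`, invisibly.
#' @export
overlay <- function(image, heatmap, path, alpha = 0.55) {
  px <- if (inherits(image, "labelled_image")) image$pixels else image
  if (length(dim(px)) == 3) px <- px[, , 1]
  hm <- heatmap$values
  if (!all(dim(px) == dim(hm)))
    stop(sprintf("shape mismatch: image is %dx%d but heatmap is %dx%d",
                 nrow(px), ncol(px), nrow(hm), ncol(hm)), call. = FALSE)
  cols <- heat_colors(hm)
  h <- nrow(px); w <- ncol(px)
  out <- array(0, c(h, 2 * w, 3))
  for (ch in 1:3) out[, 1:w, ch] <- px
  out[, w + 1:w, 1] <- (1 - alpha) * px + alpha * cols$r
  out[, w + 1:w, 2] <- (1 - alpha) * px + alpha * cols$g
  out[, w + 1:w, 3] <- (1 - alpha) * px + alpha * cols$b
  png::writePNG(clamp01(out), path)
  invisible(path)
}

#' Batch CAM overlays
#'
#' @param model a trained [count_regressor()].
#' @param dataset a [count_dataset()].
#' @param dir output directory; one `<id>-cam.png` per image.
#' @return character vector of written paths, invisibly.
#' @export
write_cam_overlays <- function(model, dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(dataset))
  hw <- model$backbone$input_size
  for (i in seq_along(dataset$items)) {
    im <- dataset$items[[i]]
    hm <- compute_cam(model, im)
    px <- im$pixels
    if (any(dim(px)[1:2] != hw)) px <- squeeze_resize(px, hw[1], hw[2])
    paths[i] <- file.path(dir, paste0(im$id, "-cam.png"))
    overlay(px, hm, paths[i])
  }
  invisible(paths)
}
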