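#' Regression head specification
#'
#' The classification output of a backbone is replaced by two fully-connected
#' layers: features map to `hidden_width` neurons (ReLU) and then to a single
#' continuous count.
#'
#' @param hidden_width neurons in the intermediate layer.
#' @param output_width must be 1 (a scalar count per image).
#' @return an object of class `regression_head_spec`.
#' @export
regression_head_spec <- function(hidden_width = 512, output_width = 1) {
  assert_that(output_width == 1, "`output_width` must be 1: one count per image")
  assert_that(hidden_width >= 1, "`hidden_width` must be >= 1")
  structure(list(hidden_width = as.integer(hidden_width), output_width = 1L),
            class = "regression_head_spec")
}

tiny_channels <- list(tiny = c(8L, 16L, 32L, 64L),
                      `tiny-wide` = c(12L, 24L, 48L, 96L))

#' Backbone specification
#'
#' The package ships a compact 4-block convolutional backbone in two widths,
#' designed for CPU-scale training on small greyscale images: four 3x3
#' convolutions (strides 1, 2, 2, 2) with ReLU, followed by global average
#' pooling. Its parameters are partitioned into three contiguous
#' learning-rate sections: blocks 1-2 (early), blocks 3-4 (late), and the
#' regression head -- the layout used by discriminative learning rates and by
#' the frozen/unfrozen training phases. No pretrained weights are available
#' for these backbones, so `pretrained` must be `FALSE`.
#'
#' @param name backbone identifier; one of `"tiny"`, `"tiny-wide"`.
#' @param pretrained must be `FALSE` (kept as an explicit configuration field
#'   so callers state the choice).
#' @param input_size `c(height, width)` of the model input in pixels.
#' @return an object of class `backbone_spec` with the derived
#'   `feature_width` and per-layer strides.
#' @export
backbone_spec <- function(name = "tiny", pretrained = FALSE,
                          input_size = c(64, 64)) {
  if (!name %in% names(tiny_channels))
    stop(sprintf("unknown backbone '%s'; supported backbones: %s",
                 name, paste(names(tiny_channels), collapse = ", ")),
         call. = FALSE)
  if (isTRUE(pretrained))
    stop("no pretrained weights ship with this package; use pretrained = FALSE",
         call. = FALSE)
  ch <- tiny_channels[[name]]
  structure(list(name = name, pretrained = FALSE,
                 channels = ch, strides = c(1L, 2L, 2L, 2L),
                 feature_width = ch[length(ch)],
                 input_size = as.integer(input_size),
                 section_layers = list(`1` = c("conv1", "conv2"),
                                       `2` = c("conv3", "conv4"),
                                       `3` = c("fc1", "fc2"))),
            class = "backbone_spec")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build a count regressor
#'
#' Assembles backbone plus two-layer regression head. The final layer is
#' zero-initialised, so an untrained model predicts 0 for every image. The
#' head holds `F*hidden + hidden + hidden*1 + 1` parameters for feature width
#' `F`.
#'
#' @param backbone a [backbone_spec()].
#' @param head a [regression_head_spec()].
#' @param seed integer seed for weight initialisation.
#' @param normalization per-channel `c(mean, sd)` applied to inputs; typically
#'   replaced by training-set statistics via [set_normalization()].
#' @return an object of class `count_regressor`.
#' @export
build_regressor <- function(backbone = backbone_spec(),
                            head = regression_head_spec(),
                            seed = 42,
                            normalization = c(mean = 0.35, sd = 0.25)) {
  assert_that(inherits(backbone, "backbone_spec"), "`backbone` must be a backbone_spec")
  assert_that(inherits(head, "regression_head_spec"),
              "`head` must be a regression_head_spec")
  ch <- backbone$channels
  cin <- c(1L, ch[-length(ch)])
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    for (l in seq_along(ch)) {
      p[[paste0("conv", l, ".w")]] <- he_init(c(3, 3, cin[l], ch[l]), 9 * cin[l])
      p[[paste0("conv", l, ".b")]] <- numeric(ch[l])
    }
    p[["fc1.w"]] <- matrix(stats::rnorm(head$hidden_width * backbone$feature_width,
                                        sd = sqrt(2 / backbone$feature_width)),
                           head$hidden_width, backbone$feature_width)
    p[["fc1.b"]] <- numeric(head$hidden_width)
    p[["fc2.w"]] <- matrix(0, 1, head$hidden_width)
    p[["fc2.b"]] <- 0
    p
  })
  structure(list(backbone = backbone, head = head, params = params,
                 normalization = normalization),
            class = "count_regressor")
}

#' @export
print.count_regressor <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<count_regressor> backbone '%s' (F=%d), head %d -> %d -> 1, %s params, input %dx%d\n",
              x$backbone$name, x$backbone$feature_width,
              x$backbone$feature_width, x$head$hidden_width,
              format(np, big.mark = ","),
              x$backbone$input_size[1], x$backbone$input_size[2]))
  invisible(x)
}

# Map a section index (1..3) to its parameter names.
section_params <- function(model, section) {
  layers <- model$backbone$section_layers[[as.character(section)]]
  as.vector(outer(layers, c(".w", ".b"), paste0))
}

# Section index of every parameter, in params order.
param_sections <- function(model) {
  out <- integer(length(model$params))
  names(out) <- names(model$params)
  for (s in 1:3) out[section_params(model, s)] <- s
  out
}

#' Number of parameters in the regression head
#' @param model a [count_regressor()].
#' @return integer parameter count of section 3.
#' @export
head_param_count <- function(model) {
  sum(vapply(model$params[section_params(model, 3)], length, numeric(1)))
}

relu <- function(z) { z[z < 0] <- 0; z }

# Forward pass over a normalised input batch (H,W,1,N).
# Returns list(out, cache); cache holds per-layer inputs and ReLU masks plus
# the last conv activations (for CAM) and head intermediates.
nn_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  nconv <- length(model$backbone$channels)
  strides <- model$backbone$strides
  a <- x
  conv_in <- vector("list", nconv); masks <- vector("list", nconv)
  for (l in seq_len(nconv)) {
    if (keep_cache) conv_in[[l]] <- a
    z <- cpp_conv2d_fwd(a, p[[paste0("conv", l, ".w")]],
                        p[[paste0("conv", l, ".b")]], strides[l], 1L)
    if (keep_cache) masks[[l]] <- z > 0
    a <- relu(z)
  }
  d <- dim(a)
  gmat <- matrix(a, d[1] * d[2], d[3] * d[4])
  g <- matrix(colMeans(gmat), d[3], d[4])              # F x N
  h1 <- p[["fc1.w"]] %*% g + p[["fc1.b"]]
  a1 <- relu(h1)
  out <- as.numeric(p[["fc2.w"]] %*% a1 + p[["fc2.b"]])
  if (!keep_cache) return(list(out = out))
  list(out = out,
       cache = list(conv_in = conv_in, masks = masks, last_act = a,
                    spatial = d[1:2], g = g, h1_mask = h1 > 0, a1 = a1,
                    n = d[4]))
}

# Backward pass from d(loss)/d(out) (length N). When `need_backbone` is FALSE
# only head gradients are produced (frozen-backbone phase).
nn_backward <- function(model, cache, dout, need_backbone = TRUE) {
  p <- model$params
  grads <- list()
  dout <- matrix(dout, 1)
  grads[["fc2.w"]] <- dout %*% t(cache$a1)
  grads[["fc2.b"]] <- sum(dout)
  da1 <- t(p[["fc2.w"]]) %*% dout
  dh1 <- da1 * cache$h1_mask
  grads[["fc1.w"]] <- dh1 %*% t(cache$g)
  grads[["fc1.b"]] <- rowSums(dh1)
  if (!need_backbone) return(grads)
  dg <- t(p[["fc1.w"]]) %*% dh1                        # F x N
  hw <- prod(cache$spatial)
  da <- array(rep(as.numeric(dg) / hw, each = hw),
              dim = c(cache$spatial, dim(dg)))
  nconv <- length(model$backbone$channels)
  strides <- model$backbone$strides
  for (l in rev(seq_len(nconv))) {
    dz <- da * cache$masks[[l]]
    res <- cpp_conv2d_bwd(cache$conv_in[[l]], p[[paste0("conv", l, ".w")]],
                          dz, strides[l], 1L, need_dx = l > 1L)
    grads[[paste0("conv", l, ".w")]] <- res$dw
    grads[[paste0("conv", l, ".b")]] <- res$db
    if (l > 1L) da <- res$dx
  }
  grads
}

#' Huber loss for count regression
#'
#' Mean over the batch of the per-element penalty: quadratic
#' `0.5 * (y - yhat)^2` for residuals below 1 in magnitude, linear
#' `|y - yhat| - 0.5` otherwise. The quadratic zone pushes near-correct
#' predictions towards exactness while the linear zone bounds the influence
#' of outlying counts, which is what makes it preferable to plain MSE for
#' long-tailed count data.
#'
#' @param predictions numeric vector of model outputs.
#' @param targets numeric vector of labels, same length.
#' @return single nonnegative number.
#' @export
huber_loss <- function(predictions, targets) {
  assert_that(length(predictions) > 0, "batches must be nonempty")
  assert_that(length(predictions) == length(targets),
              "`predictions` and `targets` must have equal length")
  r <- abs(targets - predictions)
  mean(ifelse(r < 1, 0.5 * r^2, r - 0.5))
}

# d(huber)/d(prediction); magnitude bounded by 1/n per element.
huber_grad <- function(predictions, targets) {
  n <- length(predictions)
  r <- predictions - targets
  ifelse(abs(r) < 1, r, sign(r)) / n
}

#' Input normalisation from dataset statistics
#'
#' @param model a [count_regressor()].
#' @param dataset a [count_dataset()] whose pixel mean and sd become the
#'   model's input normalisation.
#' @return the model with updated normalisation constants.
#' @export
set_normalization <- function(model, dataset) {
  px <- unlist(lapply(dataset$items, function(it) as.numeric(it$pixels)))
  model$normalization <- c(mean = mean(px), sd = max(stats::sd(px), 1e-6))
  model
}

# Stack labelled images (or matrices) into a normalised (H,W,1,N) batch,
# squeeze-resizing when sizes differ; optionally augmenting (training only).
assemble_batch <- function(model, items, policy = NULL) {
  hw <- model$backbone$input_size
  n <- length(items)
  x <- array(0, c(hw[1], hw[2], 1, n))
  for (i in seq_len(n)) {
    im <- items[[i]]
    px <- if (inherits(im, "labelled_image")) im$pixels else im
    assert_that(!is.null(px), "cannot run the model on a label-only image")
    if (length(dim(px)) == 3) px <- 0.2989 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    if (!is.null(policy)) {
      im2 <- augment(labelled_image(px, 0, "tmp"), policy)
      px <- im2$pixels
      if (any(dim(px) != hw)) px <- squeeze_resize(px, hw[1], hw[2])
    } else if (any(dim(px) != hw)) {
      px <- squeeze_resize(px, hw[1], hw[2])
    }
    x[, , 1, i] <- px
  }
  (x - model$normalization[["mean"]]) / model$normalization[["sd"]]
}

#' Predict counts for a batch of images
#'
#' Inference is deterministic for fixed weights: no augmentation is applied
#' (images are squeeze-resized to the model input size when necessary) and the
#' raw continuous outputs are returned. Rounding and clamping at zero are
#' explicit reporting options, not part of the model.
#'
#' @param model a trained [count_regressor()].
#' @param images a [count_dataset()], list of [labelled_image()]s, a single
#'   image, or a numeric matrix.
#' @param batch_size images per forward pass.
#' @param round_clamp round to the nearest integer and clamp at 0.
#' @return numeric vector with one count per image.
#' @export
predict_counts <- function(model, images, batch_size = 256, round_clamp = FALSE) {
  items <- if (inherits(images, "count_dataset")) images$items
  else if (inherits(images, "labelled_image")) list(images)
  else if (is.matrix(images)) list(images)
  else if (is.list(images)) images
  else stop("`images` must be a count_dataset, labelled_image(s) or a matrix",
            call. = FALSE)
  out <- numeric(length(items))
  for (start in seq(1, length(items), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(items))
    x <- assemble_batch(model, items[idx])
    out[idx] <- nn_forward(model, x)$out
  }
  if (round_clamp) out <- pmax(0, round(out))
  out
}

#' Save / load a model checkpoint
#'
#' Weights are stored next to a human-readable YAML manifest describing the
#' architecture, normalisation and (optionally) the epoch and validation loss
#' of the checkpoint.
#'
#' @param model a [count_regressor()].
#' @param path file stem; `<path>.rds` and `<path>.yaml` are written.
#' @param extra named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
save_regressor <- function(model, path, extra = list()) {
  saveRDS(model, paste0(path, ".rds"))
  man <- c(list(backbone = model$backbone$name,
                feature_width = model$backbone$feature_width,
                hidden_width = model$head$hidden_width,
                input_size = as.integer(model$backbone$input_size),
                normalization = as.list(model$normalization)),
           extra)
  yaml::write_yaml(man, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_regressor
#' @export
load_regressor <- function(path) readRDS(paste0(path, ".rds"))
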