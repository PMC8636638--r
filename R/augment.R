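#' Label-preserving augmentation policy
#'
#' Random transformations applied to training images only. Every transform
#' leaves the count label valid: resizing is an aspect-ratio-ignoring squeeze
#' (never a crop), horizontal flips and lighting changes are count-invariant,
#' and warping/zooming magnitudes are small enough that objects placed inside
#' the generator's border margin cannot leave the frame; zoom-out is
#' compensated with zero padding.
#'
#' @param target_height,target_width output size in pixels (squeeze-resize).
#' @param horizontal_flip_probability probability of a left-right flip.
#' @param lighting_jitter_range multiplicative intensity interval.
#' @param warp_magnitude maximal shear coefficient (fraction of image size).
#' @param max_zoom_fraction maximal zoom deviation; the zoom factor is drawn
#'   from `[1 - max_zoom_fraction, 1 + max_zoom_fraction]`. The default 0.1
#'   keeps zoom-in crops well inside the generator's 10% placement margin,
#'   since stronger zooming could cut counted objects out of the frame.
#' @return an object of class `augmentation_policy`.
#' @seealso [augment()], [set_augmentation()]
#' @export
augmentation_policy <- function(target_height = 64, target_width = 64,
                                horizontal_flip_probability = 0.5,
                                lighting_jitter_range = c(0.9, 1.1),
                                warp_magnitude = 0.06,
                                max_zoom_fraction = 0.1) {
  assert_that(horizontal_flip_probability >= 0 && horizontal_flip_probability <= 1,
              "flip probability must be in [0, 1]")
  assert_that(max_zoom_fraction >= 0 && max_zoom_fraction < 0.5,
              "`max_zoom_fraction` must be in [0, 0.5)")
  assert_that(warp_magnitude >= 0, "`warp_magnitude` must be >= 0")
  assert_that(lighting_jitter_range[1] > 0 &&
                lighting_jitter_range[1] <= lighting_jitter_range[2],
              "lighting range must be a positive ordered interval")
  structure(list(target_height = as.integer(target_height),
                 target_width = as.integer(target_width),
                 horizontal_flip_probability = horizontal_flip_probability,
                 lighting_jitter_range = lighting_jitter_range,
                 warp_magnitude = warp_magnitude,
                 max_zoom_fraction = max_zoom_fraction),
            class = "augmentation_policy")
}

#' Identity policy: squeeze-resize only
#'
#' @param target_height,target_width output size in pixels.
#' @return an [augmentation_policy()] with all random magnitudes at zero.
#' @export
identity_policy <- function(target_height = 64, target_width = 64) {
  augmentation_policy(target_height, target_width,
                      horizontal_flip_probability = 0,
                      lighting_jitter_range = c(1, 1),
                      warp_magnitude = 0, max_zoom_fraction = 0)
}

# Single bilinear resample implementing flip, shear, zoom and the squeeze to
# target size; zero fill outside the source frame implements zero padding.
affine_resample <- function(px, out_h, out_w, flip = FALSE, shear = 0, zoom = 1) {
  h <- nrow(px); w <- ncol(px)
  cy_o <- (out_h + 1) / 2; cx_o <- (out_w + 1) / 2
  cy_i <- (h + 1) / 2; cx_i <- (w + 1) / 2
  sy <- h / out_h / zoom
  sx <- w / out_w / zoom * (if (flip) -1 else 1)
  # input coords: yi = sy*(yo-cyo) + shear*h*((xo-cxo)/out_w) + cyi
  a11 <- sy; a12 <- shear * h / out_w
  a21 <- 0;  a22 <- sx
  b1 <- cy_i - a11 * cy_o - a12 * cx_o
  b2 <- cx_i - a21 * cy_o - a22 * cx_o
  cpp_affine_sample(px, c(a11, a21, a12, a22), c(b1, b2), out_h, out_w, 0)
}

#' Apply random label-preserving augmentation
#'
#' Draws flip, shear, zoom and lighting parameters (from the current RNG
#' stream, or from `seed` when given), applies them in a single bilinear
#' resample with zero fill, and squeeze-resizes to the policy's target size.
#' The label and all metadata are carried over unchanged.
#'
#' @param image a [labelled_image()] with pixels.
#' @param policy an [augmentation_policy()].
#' @param seed optional integer seed for a deterministic draw; by default the
#'   surrounding RNG stream is consumed (as during training).
#' @return the augmented [labelled_image()] at target size.
#' @export
augment <- function(image, policy, seed = NULL) {
  assert_that(inherits(image, "labelled_image") && !is.null(image$pixels),
              "`image` must be a labelled_image with pixels")
  do_one <- function() {
    flip <- runif(1) < policy$horizontal_flip_probability
    shear <- if (policy$warp_magnitude > 0)
      runif(1, -policy$warp_magnitude, policy$warp_magnitude) else 0
    zoom <- if (policy$max_zoom_fraction > 0)
      runif(1, 1 - policy$max_zoom_fraction, 1 + policy$max_zoom_fraction) else 1
    light <- if (policy$lighting_jitter_range[1] < policy$lighting_jitter_range[2])
      runif(1, policy$lighting_jitter_range[1], policy$lighting_jitter_range[2])
    else policy$lighting_jitter_range[1]
    px <- affine_resample(image$pixels, policy$target_height, policy$target_width,
                          flip = flip, shear = shear, zoom = zoom)
    clamp01(px * light)
  }
  px <- if (is.null(seed)) do_one() else withr::with_seed(as.integer(seed), do_one())
  out <- image
  out$pixels <- px
  out
}

#' Squeeze-resize an intensity matrix
#'
#' Aspect-ratio-ignoring bilinear resize (the counterpart of cropping, which
#' is never used because it could remove counted objects).
#'
#' @param px numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return numeric matrix of size `out_h x out_w`.
#' @export
squeeze_resize <- function(px, out_h, out_w) {
  affine_resample(px, out_h, out_w)
}
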