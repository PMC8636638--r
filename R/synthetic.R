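#' Dot-scene generator specification
#'
#' Describes synthetic "dot field" scenes that emulate aerial survey
#' photographs of aggregated animals: bright roughly-elliptical objects of
#' variable size and elongation on a textured background, with scene-level
#' scale (camera distance) and lighting variability, plus optional smaller
#' distractor marks (bird-like objects that are never counted).
#'
#' A scene-level scale factor is drawn once per image (all objects in one
#' photograph are at a similar distance) and, when overlap is disallowed, its
#' upper end is tapered with the requested count so that dense scenes remain
#' placeable -- mirroring how crowded haul-outs are photographed from farther
#' away and therefore contain smaller objects.
#'
#' @param image_height,image_width image size in pixels.
#' @param count_range inclusive integer interval of admissible counts.
#' @param object_scale_range object diameter as a fraction of image width.
#' @param elongation_range unitless major/minor axis ratio interval.
#' @param background_texture_amplitude amplitude of the smooth background
#'   texture, in intensity units.
#' @param lighting_jitter multiplicative intensity range applied per scene.
#' @param overlap_allowed may objects overlap each other?
#' @param distractor_count_range integer interval for the number of thin,
#'   bar-shaped distractor marks per scene.
#' @return an object of class `dot_scene_spec`.
#' @seealso [generate_dot_scene()], [make_dataset()]
#' @export
dot_scene_spec <- function(image_height = 64, image_width = 64,
                           count_range = c(0L, 30L),
                           object_scale_range = c(0.04, 0.10),
                           elongation_range = c(1.0, 1.8),
                           background_texture_amplitude = 0.05,
                           lighting_jitter = c(0.85, 1.15),
                           overlap_allowed = FALSE,
                           distractor_count_range = c(0L, 3L)) {
  assert_that(count_range[1] >= 0, "count_range lower bound must be >= 0")
  assert_that(count_range[1] <= count_range[2], "count_range must be ordered")
  assert_that(all(object_scale_range > 0) && all(object_scale_range < 0.5),
              "object_scale_range must lie within (0, 0.5)")
  assert_that(object_scale_range[1] <= object_scale_range[2],
              "object_scale_range must be ordered")
  assert_that(all(elongation_range >= 1), "elongation ratios must be >= 1")
  assert_that(lighting_jitter[1] > 0 && lighting_jitter[1] <= lighting_jitter[2],
              "lighting_jitter must be a positive ordered interval")
  assert_that(all(distractor_count_range >= 0) &&
                distractor_count_range[1] <= distractor_count_range[2],
              "distractor_count_range must be a nonnegative ordered interval")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 count_range = as.integer(count_range),
                 object_scale_range = object_scale_range,
                 elongation_range = elongation_range,
                 background_texture_amplitude = background_texture_amplitude,
                 lighting_jitter = lighting_jitter,
                 overlap_allowed = isTRUE(overlap_allowed),
                 distractor_count_range = as.integer(distractor_count_range)),
            class = "dot_scene_spec")
}

#' Ring-image generator specification
#'
#' Describes synthetic concentric-ring images that emulate otolith
#' micrographs: a bright central disc (the accessory growth centre, AGC,
#' containing no countable rings) surrounded by exactly `ring_count`
#' post-settlement rings at a fixed radial spacing, optionally magnified and
#' blurred.
#'
#' @param image_height,image_width image size in pixels.
#' @param ring_count_range inclusive integer interval of admissible ring
#'   counts; must lie within `[1, 63]`.
#' @param ring_spacing radial distance between consecutive rings, pixels.
#' @param ring_contrast peak-to-background intensity difference of a ring.
#' @param agc_radius radius of the accessory growth centre, pixels; rings are
#'   rendered strictly outside this disc.
#' @param blur_sigma Gaussian blur standard deviation, pixels.
#' @param zoom_levels set of magnification factors, one drawn per image
#'   (emulating the two microscope zoom levels of real archives).
#' @return an object of class `ring_image_spec`.
#' @seealso [generate_ring_image()]
#' @export
ring_image_spec <- function(image_height = 128, image_width = 128,
                            ring_count_range = c(1L, 28L),
                            ring_spacing = 2, ring_contrast = 0.3,
                            agc_radius = 5, blur_sigma = 0.5,
                            zoom_levels = 1) {
  assert_that(ring_count_range[1] >= 1 && ring_count_range[2] <= 63,
              "ring_count_range must lie within [1, 63]")
  assert_that(ring_count_range[1] <= ring_count_range[2],
              "ring_count_range must be ordered")
  assert_that(ring_spacing > 0 && agc_radius > 0 && ring_contrast > 0,
              "ring_spacing, agc_radius, ring_contrast must be positive")
  assert_that(all(zoom_levels > 0), "zoom levels must be positive")
  spec <- structure(list(image_height = as.integer(image_height),
                         image_width = as.integer(image_width),
                         ring_count_range = as.integer(ring_count_range),
                         ring_spacing = ring_spacing,
                         ring_contrast = ring_contrast,
                         agc_radius = agc_radius,
                         blur_sigma = blur_sigma,
                         zoom_levels = zoom_levels),
                    class = "ring_image_spec")
  check_ring_geometry(spec, ring_count_range[2])
  spec
}

check_ring_geometry <- function(spec, ring_count) {
  z <- max(spec$zoom_levels)
  need <- (spec$agc_radius + spec$ring_spacing * ring_count) * z + 2
  half <- min(spec$image_height, spec$image_width) / 2
  if (need > half)
    stop(sprintf(paste0("ring geometry does not fit: agc_radius + ",
                        "ring_spacing x %d rings (x zoom %.2f) needs %.1f px ",
                        "but the image half-width is %.1f px"),
                 ring_count, z, need, half), call. = FALSE)
  invisible(TRUE)
}

#' Undercount label-noise model
#'
#' Emulates the label noise of survey archives in which individuals appearing
#' in several partially overlapping photographs are counted only once: the
#' noisy label keeps only a random fraction of the true count, so noise is
#' undercount-only (`noisy <= true`, never negative). Images whose scene-level
#' object scale falls below a threshold are flagged unidentifiable, standing
#' in for photographs where a human recounter cannot resolve the objects.
#'
#' @param corruption_probability per-image probability that the label is
#'   corrupted.
#' @param retained_fraction_range interval in `(0, 1]`; the noisy label is
#'   `floor(true * f)` with `f` drawn uniformly from this interval.
#' @param unidentifiable_scale_threshold scene object-scale (diameter as a
#'   fraction of image width) below which an image is flagged unidentifiable.
#' @return an object of class `label_noise_model`.
#' @seealso [corrupt_labels()]
#' @export
label_noise_model <- function(corruption_probability = 0.4,
                              retained_fraction_range = c(0.4, 0.95),
                              unidentifiable_scale_threshold = 0) {
  assert_that(corruption_probability >= 0 && corruption_probability <= 1,
              "corruption_probability must be in [0, 1]")
  assert_that(retained_fraction_range[1] > 0 &&
                retained_fraction_range[1] <= retained_fraction_range[2] &&
                retained_fraction_range[2] <= 1,
              "retained_fraction_range must be an ordered interval in (0, 1]")
  structure(list(corruption_probability = corruption_probability,
                 retained_fraction_range = retained_fraction_range,
                 unidentifiable_scale_threshold = unidentifiable_scale_threshold),
            class = "label_noise_model")
}

# Smooth background texture in [-1, 1]: a coarse uniform grid interpolated
# bilinearly to image size.
smooth_noise <- function(h, w, cells = 6) {
  g <- matrix(runif((cells + 1) * (cells + 1), -1, 1), cells + 1)
  ys <- seq(1, cells + 1, length.out = h)
  xs <- seq(1, cells + 1, length.out = w)
  y0 <- pmin(floor(ys), cells); x0 <- pmin(floor(xs), cells)
  fy <- ys - y0; fx <- xs - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fym <- rep(fy, w); fxm <- rep(fx, each = h)
  v <- a * (1 - fym) * (1 - fxm) + b * fym * (1 - fxm) +
    cc * (1 - fym) * fxm + d * fym * fxm
  matrix(v, h, w)
}

# Anti-aliased ellipse composited onto `canvas` (modified in place via return).
draw_ellipse <- function(canvas, cy, cx, a, b, angle, intensity) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- max(a, b) + 1.5
  y1 <- max(1, floor(cy - r)); y2 <- min(h, ceiling(cy + r))
  x1 <- max(1, floor(cx - r)); x2 <- min(w, ceiling(cx + r))
  if (y1 > y2 || x1 > x2) return(canvas)
  ys <- y1:y2; xs <- x1:x2
  dy <- matrix(ys - cy, length(ys), length(xs))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- cos(angle) * dx + sin(angle) * dy
  v <- -sin(angle) * dx + cos(angle) * dy
  rho <- sqrt((u / a)^2 + (v / b)^2)
  alpha <- clamp01((1 - rho) * min(a, b) + 0.5)
  patch <- canvas[ys, xs, drop = FALSE]
  canvas[ys, xs] <- patch * (1 - alpha) + intensity * alpha
  canvas
}

# Scene-level scale cap so that `count` non-overlapping objects remain
# placeable inside the margin box. Random sequential placement saturates well
# below the jamming density, hence the 0.3 area budget; the effective
# exclusion radius accounts for the worst-case elongation and per-object size
# jitter on top of the half-gap.
dot_scale_cap <- function(spec, count) {
  if (spec$overlap_allowed || count <= 1) return(spec$object_scale_range[2])
  m <- ceiling(0.1 * min(spec$image_height, spec$image_width))
  area <- (spec$image_height - 2 * m) * (spec$image_width - 2 * m)
  infl <- sqrt(spec$elongation_range[2]) * 1.15
  r_cap <- (sqrt(0.3 * area / (pi * count)) - 1) / infl
  min(spec$object_scale_range[2],
      max(spec$object_scale_range[1], 2 * r_cap / spec$image_width))
}

#' Generate one synthetic dot scene
#'
#' Renders exactly `count` anti-aliased elliptical objects (plus any
#' distractor marks, which are never counted) on a textured background, with
#' per-scene scale and lighting variation. Identical `(spec, count, seed)`
#' arguments yield bit-identical images.
#'
#' @param spec a [dot_scene_spec()].
#' @param count integer number of counted objects; must lie in
#'   `spec$count_range`.
#' @param seed integer seed controlling every random choice in the scene.
#' @return a [labelled_image()] with `label == count`; object geometry is kept
#'   in `meta$objects` and the scene scale in `meta$scene_scale`.
#' @export
generate_dot_scene <- function(spec, count, seed) {
  assert_that(inherits(spec, "dot_scene_spec"), "`spec` must be a dot_scene_spec")
  if (count < spec$count_range[1] || count > spec$count_range[2])
    stop(sprintf("count %d outside the spec's count_range [%d, %d]",
                 count, spec$count_range[1], spec$count_range[2]), call. = FALSE)
  h <- spec$image_height; w <- spec$image_width
  withr::with_seed(as.integer(seed), {
    margin <- ceiling(0.1 * min(h, w))
    scene_scale <- runif(1, spec$object_scale_range[1], dot_scale_cap(spec, count))
    place <- function(n, mean_diam, thin) {
      rows <- vector("list", n)
      accepted <- 0L; attempts <- 0L
      while (accepted < n) {
        attempts <- attempts + 1L
        if (attempts > 1500L * max(n, 1L))
          stop("could not place all objects without overlap; reduce count or object scale",
               call. = FALSE)
        diam <- mean_diam * runif(1, 0.85, 1.15)
        if (thin) {
          a <- max(1.2, diam * 0.7); b <- 0.55
        } else {
          e <- runif(1, spec$elongation_range[1], spec$elongation_range[2])
          a <- (diam / 2) * sqrt(e); b <- (diam / 2) / sqrt(e)
        }
        bound <- a
        if (2 * (margin + bound) >= min(h, w))
          stop("object too large for the placement margin", call. = FALSE)
        cy <- runif(1, margin + bound, h - margin - bound)
        cx <- runif(1, margin + bound, w - margin - bound)
        ok <- TRUE
        if (!spec$overlap_allowed || thin) {
          for (prev in c(placed, rows[seq_len(accepted)])) {
            if (sqrt((cy - prev$cy)^2 + (cx - prev$cx)^2) <
                bound + prev$bound + 2) { ok <- FALSE; break }
          }
        }
        if (ok) {
          accepted <- accepted + 1L
          rows[[accepted]] <- list(cy = cy, cx = cx, a = a, b = b,
                                   angle = runif(1, 0, pi), bound = bound,
                                   intensity = runif(1, 0.6, 0.95))
        }
      }
      rows
    }
    placed <- list()
    objects <- place(count, scene_scale * w, thin = FALSE)
    placed <- objects
    ds <- spec$distractor_count_range
    n_dis <- if (ds[2] > ds[1]) sample(ds[1]:ds[2], 1) else ds[1]
    distractors <- place(n_dis, scene_scale * w, thin = TRUE)

    canvas <- matrix(0.12, h, w)
    if (spec$background_texture_amplitude > 0)
      canvas <- canvas + spec$background_texture_amplitude * smooth_noise(h, w)
    for (o in c(objects, distractors))
      canvas <- draw_ellipse(canvas, o$cy, o$cx, o$a, o$b, o$angle, o$intensity)
    lighting <- runif(1, spec$lighting_jitter[1], spec$lighting_jitter[2])
    canvas <- clamp01(canvas * lighting)

    geom <- function(rows, type) {
      if (!length(rows)) return(NULL)
      data.frame(cy = vapply(rows, `[[`, 1, "cy"), cx = vapply(rows, `[[`, 1, "cx"),
                 a = vapply(rows, `[[`, 1, "a"), b = vapply(rows, `[[`, 1, "b"),
                 angle = vapply(rows, `[[`, 1, "angle"),
                 intensity = vapply(rows, `[[`, 1, "intensity"),
                 type = type)
    }
    labelled_image(canvas, count,
                   id = sprintf("dot-c%03d-s%d", count, as.integer(seed)),
                   meta = list(kind = "dot",
                               objects = rbind(geom(objects, "counted"),
                                               geom(distractors, "distractor")),
                               scene_scale = scene_scale,
                               lighting = lighting))
  })
}

#' Generate one synthetic concentric-ring image
#'
#' Renders a bright accessory-growth-centre disc surrounded by exactly
#' `ring_count` concentric rings, then applies magnification, Gaussian blur
#' and a small random centre offset. Identical `(spec, ring_count, seed)`
#' arguments yield bit-identical images.
#'
#' @param spec a [ring_image_spec()].
#' @param ring_count number of rings outside the AGC disc; must lie in
#'   `spec$ring_count_range`.
#' @param seed integer seed.
#' @return a [labelled_image()] with `label == ring_count`; the effective
#'   (zoomed) geometry is kept in `meta`.
#' @export
generate_ring_image <- function(spec, ring_count, seed) {
  assert_that(inherits(spec, "ring_image_spec"), "`spec` must be a ring_image_spec")
  if (ring_count < spec$ring_count_range[1] || ring_count > spec$ring_count_range[2])
    stop(sprintf("ring_count %d outside the spec's ring_count_range [%d, %d]",
                 ring_count, spec$ring_count_range[1], spec$ring_count_range[2]),
         call. = FALSE)
  check_ring_geometry(spec, ring_count)
  h <- spec$image_height; w <- spec$image_width
  withr::with_seed(as.integer(seed), {
    z <- if (length(spec$zoom_levels) > 1) sample(spec$zoom_levels, 1) else spec$zoom_levels
    sp <- spec$ring_spacing * z
    ag <- spec$agc_radius * z
    cy <- (h + 1) / 2 + runif(1, -2, 2)
    cx <- (w + 1) / 2 + runif(1, -2, 2)
    base <- 0.45 + runif(1, -0.03, 0.03)
    r <- sqrt(outer((1:h - cy)^2, (1:w - cx)^2, `+`))
    img <- matrix(base, h, w)
    band <- r > ag & r <= ag + sp * ring_count
    img[band] <- base + spec$ring_contrast * 0.5 *
      (1 - cos(2 * pi * (r[band] - ag) / sp))
    agc <- r <= ag
    img[agc] <- base + 0.18 * (1 - (r[agc] / ag)^2)
    if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
    img <- clamp01(img)
    labelled_image(img, ring_count,
                   id = sprintf("ring-c%03d-s%d", ring_count, as.integer(seed)),
                   meta = list(kind = "ring", zoom = z, spacing = sp,
                               agc_radius = ag, center = c(cy, cx)))
  })
}

# Edge-normalised Gaussian blur built on the package's own conv kernel.
gaussian_blur <- function(img, sigma) {
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  g <- stats::dnorm(seq(-(k - 1) / 2, (k - 1) / 2), sd = sigma)
  ker <- outer(g, g); ker <- ker / sum(ker)
  pad <- (k - 1L) %/% 2L
  wrap <- function(m) {
    x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
    wk <- array(ker, c(k, k, 1L, 1L))
    drop(cpp_conv2d_fwd(x, wk, 0, 1L, pad))
  }
  wrap(img) / wrap(matrix(1, nrow(img), ncol(img)))
}

#' Right-skewed count weights
#'
#' Default label distribution for synthetic datasets: geometric-style decay
#' over the count range, so images with high counts are scarce -- the
#' hallmark of real survey archives.
#'
#' @param count_range inclusive integer interval.
#' @param rate decay rate over the normalised range (larger = more skew).
#' @return named numeric vector of unnormalised weights over
#'   `count_range[1]:count_range[2]`.
#' @export
skewed_count_weights <- function(count_range, rate = 3) {
  counts <- count_range[1]:count_range[2]
  span <- max(1L, count_range[2] - count_range[1])
  w <- exp(-rate * (counts - count_range[1]) / span)
  names(w) <- counts
  w
}

#' Generate a synthetic dataset
#'
#' Draws `n_images` labels from a categorical distribution over the spec's
#' count range and renders one image per label, with per-image seeds derived
#' from `seed` so the whole dataset is reproducible from a single integer.
#'
#' @param spec a [dot_scene_spec()] or [ring_image_spec()].
#' @param n_images number of images to generate.
#' @param count_distribution named numeric vector of nonnegative weights
#'   (names are counts); defaults to [skewed_count_weights()] over the spec's
#'   range.
#' @param seed integer seed.
#' @param id_prefix prefix of the generated item ids (default: `"dot"` or
#'   `"ring"` per spec); use distinct prefixes when datasets will be merged.
#' @return a [count_dataset()] of `n_images` items.
#' @export
make_dataset <- function(spec, n_images, count_distribution = NULL, seed = 1,
                         id_prefix = NULL) {
  assert_that(n_images >= 1, "`n_images` must be >= 1")
  rng <- if (inherits(spec, "dot_scene_spec")) spec$count_range
  else if (inherits(spec, "ring_image_spec")) spec$ring_count_range
  else stop("`spec` must be a dot_scene_spec or ring_image_spec", call. = FALSE)
  if (is.null(count_distribution)) count_distribution <- skewed_count_weights(rng)
  assert_that(!is.null(names(count_distribution)),
              "`count_distribution` must be named by counts")
  assert_that(all(count_distribution >= 0) && any(count_distribution > 0),
              "weights must be nonnegative and not all zero")
  counts <- as.integer(names(count_distribution))
  assert_that(all(counts >= rng[1] & counts <= rng[2]),
              "count_distribution names must lie within the spec's count range")
  lab <- withr::with_seed(derive_seed(seed, 1),
                          counts[sample.int(length(counts), n_images,
                                            replace = TRUE,
                                            prob = count_distribution)])
  gen <- if (inherits(spec, "dot_scene_spec")) generate_dot_scene else generate_ring_image
  if (is.null(id_prefix))
    id_prefix <- if (inherits(spec, "dot_scene_spec")) "dot" else "ring"
  items <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    im <- gen(spec, lab[i], derive_seed(seed, 1000 + i))
    im$id <- sprintf("%s-%06d", id_prefix, i)
    items[[i]] <- im
  }
  count_dataset(items)
}

#' Corrupt dataset labels with undercount noise
#'
#' Applies a [label_noise_model()]: with the model's corruption probability an
#' image's label is replaced by `floor(true * f)` with `f` drawn from the
#' retained-fraction range; the true label is preserved in metadata and
#' corrupted items gain the `noisy` flag. Images whose scene object scale is
#' below the unidentifiability threshold are flagged `unidentifiable`
#' regardless of the corruption coin.
#'
#' @param dataset a [count_dataset()] whose labels are true counts.
#' @param noise a [label_noise_model()].
#' @param seed integer seed.
#' @return the dataset with noisy labels.
#' @export
corrupt_labels <- function(dataset, noise, seed = 1) {
  assert_that(inherits(noise, "label_noise_model"),
              "`noise` must be a label_noise_model")
  n <- length(dataset)
  withr::with_seed(derive_seed(seed, 2), {
    coin <- runif(n) < noise$corruption_probability
    f <- runif(n, noise$retained_fraction_range[1], noise$retained_fraction_range[2])
    for (i in seq_len(n)) {
      it <- dataset$items[[i]]
      it$true_label <- it$label
      if (coin[i]) {
        it$label <- as.integer(floor(it$label * f[i]))
        it$flags$noisy <- TRUE
      }
      sc <- it$meta$scene_scale
      if (!is.null(sc) && sc < noise$unidentifiable_scale_threshold)
        it$flags$unidentifiable <- TRUE
      dataset$items[[i]] <- it
    }
  })
  dataset
}

#' Relabelling oracle
#'
#' Stands in for the human recounter of the refinement loop: returns the
#' verified true count of an image, or the unidentifiable signal
#' (`NA_integer_`) when the image is flagged as not recountable.
#'
#' @param image a [labelled_image()] carrying true-label metadata.
#' @return integer count, or `NA_integer_` for unidentifiable images.
#' @export
oracle_relabel <- function(image) {
  assert_that(inherits(image, "labelled_image"), "`image` must be a labelled_image")
  if (is.null(image$true_label))
    stop(sprintf("image %s carries no true-label metadata; the oracle cannot recount it",
                 image$id), call. = FALSE)
  if (image$flags$unidentifiable) return(NA_integer_)
  image$true_label
}

#' Ground-truth object mask of a synthetic dot scene
#'
#' @param image a [labelled_image()] generated by [generate_dot_scene()].
#' @param type `"counted"` for the labelled objects, `"distractor"` for the
#'   bird-like marks.
#' @return logical matrix of the image size, `TRUE` inside the objects.
#' @export
object_mask <- function(image, type = c("counted", "distractor")) {
  type <- match.arg(type)
  obj <- image$meta$objects
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  mask <- matrix(FALSE, h, w)
  if (is.null(obj)) return(mask)
  obj <- obj[obj$type == type, , drop = FALSE]
  yy <- matrix(1:h, h, w); xx <- matrix(1:w, h, w, byrow = TRUE)
  for (i in seq_len(nrow(obj))) {
    u <- cos(obj$angle[i]) * (xx - obj$cx[i]) + sin(obj$angle[i]) * (yy - obj$cy[i])
    v <- -sin(obj$angle[i]) * (xx - obj$cx[i]) + cos(obj$angle[i]) * (yy - obj$cy[i])
    mask <- mask | ((u / obj$a[i])^2 + (v / obj$b[i])^2 <= 1)
  }
  mask
}

#' Radial intensity profile of a ring image
#'
#' Mean intensity as a function of distance from the ring centre, used to
#' verify that a rendered image carries exactly the labelled number of rings.
#'
#' @param image a [labelled_image()] from [generate_ring_image()].
#' @param bin_width radial bin width in pixels.
#' @return data frame with columns `radius` (bin midpoint) and `intensity`.
#' @export
radial_profile <- function(image, bin_width = 0.5) {
  ctr <- image$meta$center %||% ((dim(image$pixels) + 1) / 2)
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  r <- sqrt(outer((1:h - ctr[1])^2, (1:w - ctr[2])^2, `+`))
  bins <- floor(r / bin_width)
  means <- tapply(as.vector(image$pixels), as.vector(bins), mean)
  data.frame(radius = (as.numeric(names(means)) + 0.5) * bin_width,
             intensity = as.numeric(means))
}
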