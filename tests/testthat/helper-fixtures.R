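# Shared fixtures: specs without nuisance factors (for exact counting
# oracles), label-only datasets for split arithmetic, and the independent
# connected-component / radial-peak oracles.

# Dot spec with no texture, lighting or distractors: thresholding at 0.35
# cleanly separates objects from background, so connected components count
# the objects exactly.
clean_dot_spec <- function(...) {
  dot_scene_spec(background_texture_amplitude = 0,
                 lighting_jitter = c(1, 1),
                 distractor_count_range = c(0L, 0L), ...)
}

# Independent count oracle: connected components of the thresholded render.
cc_count <- function(pixels, threshold = 0.35) {
  max(EBImage::bwlabel(pixels > threshold))
}

# Independent ring-count oracle: strict local maxima of the lightly smoothed
# radial intensity profile beyond the accessory growth centre.
ring_peak_count <- function(image) {
  p <- radial_profile(image)
  v <- as.numeric(stats::filter(p$intensity, rep(1 / 3, 3)))
  pk <- which(diff(sign(diff(v))) == -2) + 1
  sum(p$radius[pk] > image$meta$agc_radius, na.rm = TRUE)
}

# Pixel-free dataset for split/selection arithmetic at realistic sizes.
label_only_dataset <- function(labels, prefix = "it", noisy = FALSE,
                               unidentifiable = rep(FALSE, length(labels)),
                               true_labels = labels) {
  items <- lapply(seq_along(labels), function(i)
    labelled_image(NULL, labels[i], sprintf("%s-%05d", prefix, i),
                   true_label = true_labels[i], noisy = noisy,
                   unidentifiable = unidentifiable[i]))
  count_dataset(items)
}

# Small rendered dataset for training-contract tests.
tiny_dot_dataset <- function(n, seed, counts = 0:8) {
  make_dataset(dot_scene_spec(count_range = c(min(counts), max(counts))),
               n, stats::setNames(rep(1, length(counts)), counts), seed = seed)
}

# Brute-force reference for tail selection with discard-and-replace: walk the
# sorted records from each end, skipping unidentifiable images.
brute_force_selection <- function(records, flagged_ids, k_over, k_under) {
  pick <- function(order_idx, k, taken) {
    sel <- character(0)
    for (i in order_idx) {
      if (length(sel) >= k) break
      id <- records$id[i]
      if (id %in% taken || id %in% flagged_ids) next
      sel <- c(sel, id)
    }
    sel
  }
  over <- pick(seq_len(nrow(records)), k_over, character(0))
  under <- pick(rev(seq_len(nrow(records))), k_under, over)
  list(over = over, under = under)
}
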