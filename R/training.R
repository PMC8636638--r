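#' One-cycle learning-rate schedule specification
#'
#' The learning rate rises from `base_lr / start_dampening` to
#' `base_lr * max_lr_multiplier` over the warm-up fraction of the run
#' (cosine), then anneals to `base_lr / end_dampening` (cosine). The schedule
#' attains its maximum exactly once and ends below its starting value.
#'
#' @param max_lr_multiplier peak learning rate as a multiple of the base rate.
#' @param warmup_fraction fraction of total steps spent rising.
#' @param start_dampening divisor applied to the base rate at step 0.
#' @param end_dampening divisor applied at the final step.
#' @return an object of class `one_cycle_spec`.
#' @export
one_cycle_spec <- function(max_lr_multiplier = 1, warmup_fraction = 0.3,
                           start_dampening = 25, end_dampening = 1e4) {
  assert_that(warmup_fraction > 0 && warmup_fraction < 1,
              "`warmup_fraction` must lie in (0, 1)")
  assert_that(start_dampening > 1 && end_dampening >= start_dampening,
              "dampening factors must satisfy end >= start > 1")
  assert_that(max_lr_multiplier > 0, "`max_lr_multiplier` must be positive")
  structure(list(max_lr_multiplier = max_lr_multiplier,
                 warmup_fraction = warmup_fraction,
                 start_dampening = start_dampening,
                 end_dampening = end_dampening),
            class = "one_cycle_spec")
}

#' One-cycle learning rate at a given step
#'
#' @param step step index in `0:(total_steps - 1)` (vectorised).
#' @param total_steps total number of optimisation steps; must be positive.
#' @param base_lr base learning rate of the section.
#' @param cycle a [one_cycle_spec()].
#' @return learning rate(s).
#' @export
one_cycle_lr <- function(step, total_steps, base_lr, cycle = one_cycle_spec()) {
  if (total_steps <= 0) stop("`total_steps` must be positive", call. = FALSE)
  assert_that(all(step >= 0 & step < total_steps),
              "`step` must lie in [0, total_steps)")
  peak <- base_lr * cycle$max_lr_multiplier
  lo0 <- base_lr / cycle$start_dampening
  lo1 <- base_lr / cycle$end_dampening
  warm <- max(1, ceiling(cycle$warmup_fraction * total_steps))
  warm <- min(warm, total_steps - 1)
  if (warm < 1) return(rep(peak, length(step)))
  up <- function(s) lo0 + (peak - lo0) * (1 - cos(pi * s / warm)) / 2
  down <- function(s) lo1 + (peak - lo1) *
    (1 + cos(pi * (s - warm) / (total_steps - 1 - warm))) / 2
  ifelse(step <= warm, up(step), down(step))
}

#' Training-phase specification
#'
#' @param epochs number of passes over the training set.
#' @param section_lrs base learning rates for the three model sections
#'   (early backbone, late backbone, head), nondecreasing; a single value is
#'   recycled. See [discriminative_lrs()].
#' @param frozen_sections subset of `c(1, 2)` whose parameters are not
#'   updated; the head (section 3) can never be frozen.
#' @param cycle a [one_cycle_spec()].
#' @return an object of class `phase_spec`.
#' @export
phase_spec <- function(epochs, section_lrs, frozen_sections = integer(),
                       cycle = one_cycle_spec()) {
  assert_that(epochs >= 0, "`epochs` must be >= 0")
  if (length(section_lrs) == 1) section_lrs <- rep(section_lrs, 3)
  assert_that(length(section_lrs) == 3, "`section_lrs` must have 3 entries")
  assert_that(!is.unsorted(section_lrs),
              "section learning rates must be nondecreasing (early <= late <= head)")
  assert_that(all(frozen_sections %in% 1:2),
              "only backbone sections 1 and 2 may be frozen; the head never is")
  structure(list(epochs = as.integer(epochs), section_lrs = section_lrs,
                 frozen_sections = as.integer(frozen_sections), cycle = cycle),
            class = "phase_spec")
}

#' Discriminative learning rates over three sections
#'
#' The early backbone section trains at `low`, the head at `high`, and the
#' middle section at their geometric mean.
#'
#' @param low,high endpoints of the learning-rate range.
#' @return numeric vector of 3 nondecreasing rates.
#' @export
discriminative_lrs <- function(low, high) {
  assert_that(low > 0 && high >= low, "need 0 < low <= high")
  c(low, sqrt(low * high), high)
}

#' Training configuration
#'
#' @param batch_size images per optimisation step.
#' @param seed integer seed driving shuffling and augmentation draws.
#' @param weight_decay decoupled weight decay applied to weights (not biases).
#' @param betas Adam moment coefficients.
#' @param eps Adam numerical floor.
#' @param verbose emit one line per epoch to stderr.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 64, seed = 1, weight_decay = 0.01,
                         betas = c(0.9, 0.99), eps = 1e-8, verbose = FALSE) {
  assert_that(batch_size >= 1, "`batch_size` must be >= 1")
  structure(list(batch_size = as.integer(batch_size), seed = as.integer(seed),
                 weight_decay = weight_decay, betas = betas, eps = eps,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lrs, config) {
  state$t <- state$t + 1L
  b1 <- config$betas[1]; b2 <- config$betas[2]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    step <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + config$eps)
    lr <- lrs[[nm]]
    if (config$weight_decay > 0 && grepl("\\.w$", nm))
      params[[nm]] <- params[[nm]] * (1 - lr * config$weight_decay)
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}

validation_loss <- function(model, val_set, batch_size = 256) {
  preds <- predict_counts(model, val_set, batch_size = batch_size)
  huber_loss(preds, labels(val_set))
}

#' Train one phase
#'
#' Runs `phase$epochs` passes of Huber-loss optimisation with the one-cycle
#' schedule applied to each section's base rate, honouring frozen sections
#' (their parameters are bit-identical before and after). Augmentation uses
#' the policy attached to the training set; validation always runs on
#' un-augmented images. The returned model is the checkpoint with minimum
#' validation loss over the recorded epochs.
#'
#' @param model a [count_regressor()].
#' @param train_set,val_set nonempty [count_dataset()]s; attach an
#'   augmentation policy to `train_set` only (see [set_augmentation()]).
#' @param phase a [phase_spec()].
#' @param config a [train_config()].
#' @return list with elements `model` (best checkpoint) and `history` (data
#'   frame of `epoch`, `train_loss`, `val_loss`, `lr_head`).
#' @export
train_phase <- function(model, train_set, val_set, phase, config = train_config()) {
  assert_that(inherits(phase, "phase_spec"), "`phase` must be a phase_spec")
  assert_that(length(train_set) >= 1 && length(val_set) >= 1,
              "training and validation sets must be nonempty")
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr_head = numeric())
  if (phase$epochs == 0) return(list(model = model, history = history))

  secs <- param_sections(model)
  frozen <- names(secs)[secs %in% phase$frozen_sections]
  active <- setdiff(names(secs), frozen)
  backbone_active <- any(secs[active] < 3)
  n <- length(train_set)
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- steps_per_epoch * phase$epochs
  labs <- labels(train_set)
  policy <- train_set$augmentation

  opt <- adam_state(model$params[active])
  best_val <- Inf; best_params <- model$params
  step <- 0L
  withr::with_seed(derive_seed(config$seed, 21), {
    for (epoch in seq_len(phase$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b in seq_len(steps_per_epoch)) {
        idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
        x <- assemble_batch(model, train_set$items[idx], policy = policy)
        fwd <- nn_forward(model, x, keep_cache = TRUE)
        loss <- huber_loss(fwd$out, labs[idx])
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
        ep_loss <- ep_loss + loss * length(idx)
        grads <- nn_backward(model, fwd$cache, huber_grad(fwd$out, labs[idx]),
                             need_backbone = backbone_active)
        grads <- grads[intersect(names(grads), active)]
        lrs <- lapply(secs[names(grads)], function(s)
          one_cycle_lr(step, total_steps, phase$section_lrs[s], phase$cycle))
        upd <- adam_update(model$params[names(grads)], grads, opt, lrs, config)
        model$params[names(grads)] <- upd$params
        opt <- upd$state
        step <- step + 1L
      }
      tr <- ep_loss / n
      vl <- validation_loss(model, val_set)
      if (!is.finite(vl))
        stop(sprintf("non-finite validation loss at epoch %d", epoch), call. = FALSE)
      lr_now <- one_cycle_lr(step - 1L, total_steps, phase$section_lrs[3], phase$cycle)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tr,
                                           val_loss = vl, lr_head = lr_now))
      if (config$verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                        epoch, tr, vl, lr_now))
      if (vl < best_val) { best_val <- vl; best_params <- model$params }
    }
  })
  model$params <- best_params
  list(model = model, history = history)
}

#' Run the two-phase training protocol
#'
#' Phase one trains only the regression head (backbone sections frozen);
#' phase two unfreezes the whole network and fine-tunes it with
#' discriminative learning rates. Each phase keeps its best-validation-epoch
#' checkpoint.
#'
#' @param model a [count_regressor()].
#' @param train_set,val_set [count_dataset()]s (augmentation policy on the
#'   training set only).
#' @param head_phase,finetune_phase [phase_spec()]s; `head_phase` is forced to
#'   freeze sections 1-2.
#' @param config a [train_config()].
#' @return the trained model; phase histories are attached as attribute
#'   `"history"` (list of data frames).
#' @export
run_protocol <- function(model, train_set, val_set, head_phase, finetune_phase,
                         config = train_config()) {
  head_phase$frozen_sections <- 1:2
  p1 <- train_phase(model, train_set, val_set, head_phase, config)
  p2 <- train_phase(p1$model, train_set, val_set, finetune_phase, config)
  out <- p2$model
  attr(out, "history") <- list(head = p1$history, finetune = p2$history)
  out
}

#' Published training protocols
#'
#' The two training recipes used for the original otolith-ring and seal
#' experiments, kept verbatim as presets: the otolith recipe trains the head
#' for 25 epochs at LR 5e-2 and fine-tunes all layers for 50 epochs with
#' discriminative LRs 9e-7..9e-5 (batch 84); the seal recipe trains the head
#' for 50 epochs at 3e-2 and fine-tunes 50 epochs at 3e-4..3e-2 (batch 100).
#' These rates were tuned for an ImageNet-pretrained residual backbone and
#' large images; [desk_protocol()] is the counterpart scaled to the
#' package's tiny backbone.
#'
#' @param scenario `"otolith"` or `"seal"`.
#' @return list with `head_phase`, `finetune_phase`, `batch_size`.
#' @export
protocol_preset <- function(scenario = c("otolith", "seal")) {
  scenario <- match.arg(scenario)
  if (scenario == "otolith") {
    list(head_phase = phase_spec(25, c(5e-2, 5e-2, 5e-2), frozen_sections = 1:2),
         finetune_phase = phase_spec(50, discriminative_lrs(9e-7, 9e-5)),
         batch_size = 84L)
  } else {
    list(head_phase = phase_spec(50, c(3e-2, 3e-2, 3e-2), frozen_sections = 1:2),
         finetune_phase = phase_spec(50, discriminative_lrs(3e-4, 3e-2)),
         batch_size = 100L)
  }
}

#' Desk-scale training protocol for the tiny backbone
#'
#' Defaults chosen for CPU-scale runs on 64x64 synthetic scenes with a
#' randomly initialised tiny backbone: a short head-only phase followed by a
#' full fine-tune with discriminative learning rates.
#'
#' @param head_epochs,finetune_epochs epochs per phase.
#' @param head_lr head-phase learning rate.
#' @param finetune_lrs endpoints of the discriminative fine-tune range.
#' @return list with `head_phase` and `finetune_phase`.
#' @export
desk_protocol <- function(head_epochs = 3, finetune_epochs = 12,
                          head_lr = 1e-2, finetune_lrs = c(2e-4, 2e-3)) {
  list(head_phase = phase_spec(head_epochs, head_lr, frozen_sections = 1:2),
       finetune_phase = phase_spec(finetune_epochs,
                                   discriminative_lrs(finetune_lrs[1],
                                                      finetune_lrs[2])))
}
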