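#' Training configuration
#'
#' Hyperparameters of the two-stage training loop. Defaults are the desk
#' scale used throughout the package's tests (30 + 30 epochs, 10 batches of
#' 2); \code{train_preset("paper_scale")} gives the full-scale schedule
#' (300 + 300 epochs, 250 batches of 2). The learning-rate rule: if the
#' exponential moving average of the training loss has not decreased by
#' \code{lr_min_improvement} within the last \code{lr_patience_epochs}
#' epochs, the learning rate is divided by \code{lr_decay_factor}; after a
#' decay the rule stays quiet for one full patience window.
#'
#' @param stage1_epochs,stage2_epochs epochs per stage.
#' @param batches_per_epoch optimisation steps per epoch.
#' @param batch_size volumes per step.
#' @param lr_init initial Adam learning rate (3e-4).
#' @param lr_decay_factor divide the learning rate by this on plateau (5).
#' @param lr_patience_epochs plateau window length in epochs (30).
#' @param lr_min_improvement required EMA-loss decrease over the window (5e-3).
#' @param ema_alpha smoothing weight on the previous EMA value (0.9).
#' @param seed integer seed governing initialisation and batch sampling.
#' @param mask_refresh when stage 2 rebuilds error masks: \code{"per_batch"}
#'   (default, masks always reflect the current network) or
#'   \code{"per_epoch"} (masks cached at each epoch start).
#' @param lr_reset_stage2 restart the learning-rate schedule at
#'   \code{lr_init} for stage 2 (default TRUE).
#' @param monitor_subjects size of the fixed monitoring subset on which
#'   per-epoch Dice and mis-seg voxel counts are logged.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(stage1_epochs = 30L, stage2_epochs = 30L,
                         batches_per_epoch = 10L, batch_size = 2L,
                         lr_init = 3e-4, lr_decay_factor = 5,
                         lr_patience_epochs = 30L, lr_min_improvement = 5e-3,
                         ema_alpha = 0.9, seed = 1L,
                         mask_refresh = c("per_batch", "per_epoch"),
                         lr_reset_stage2 = TRUE, monitor_subjects = 4L) {
  mask_refresh <- match.arg(mask_refresh)
  # YAML configs may deliver numerics as strings ("3e-4"); coerce up front
  lr_init <- as.numeric(lr_init)
  lr_decay_factor <- as.numeric(lr_decay_factor)
  lr_min_improvement <- as.numeric(lr_min_improvement)
  ema_alpha <- as.numeric(ema_alpha)
  stopifnot(stage1_epochs >= 0, stage2_epochs >= 0, batches_per_epoch >= 1,
            batch_size >= 1, lr_init > 0, lr_decay_factor > 1,
            lr_patience_epochs >= 1, lr_min_improvement > 0,
            ema_alpha > 0, ema_alpha < 1, monitor_subjects >= 1)
  structure(list(stage1_epochs = as.integer(stage1_epochs),
                 stage2_epochs = as.integer(stage2_epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_decay_factor = lr_decay_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 lr_min_improvement = lr_min_improvement,
                 ema_alpha = ema_alpha, seed = as.integer(seed),
                 mask_refresh = mask_refresh,
                 lr_reset_stage2 = isTRUE(lr_reset_stage2),
                 monitor_subjects = as.integer(monitor_subjects)),
            class = "train_config")
}

#' Full-scale or desk-scale training schedules
#' @param name "desk" or "paper_scale".
#' @param ... overrides passed to \code{\link{train_config}}.
#' @return a \code{\link{train_config}}.
#' @export
train_preset <- function(name, ...) {
  base <- switch(name,
    # at desk scale (600 steps/stage) the full-scale rate of 3e-4 leaves
    # stage 1 far from its plateau, and the refinement stage presupposes a
    # converged coarse stage; the desk preset scales the rate accordingly
    desk = list(lr_init = 3e-3),
    paper_scale = list(stage1_epochs = 300L, stage2_epochs = 300L,
                       batches_per_epoch = 250L, batch_size = 2L),
    stop("unknown train preset: ", name))
  do.call(train_config, modifyList(base, list(...)))
}

#' Plateau-based learning-rate decay step
#'
#' Applies the decay rule to an EMA-loss history: when the best EMA value
#' inside the last \code{lr_patience_epochs} epochs fails to improve on the
#' best value seen before that window by at least \code{lr_min_improvement},
#' the learning rate is divided by \code{lr_decay_factor}. No decision is
#' taken until a full window of history exists, and no second decay can
#' occur within \code{lr_patience_epochs} epochs of the previous one
#' (cool-down), so cascaded decays on one plateau are impossible.
#'
#' @param ema_history numeric vector of per-epoch EMA training losses
#'   (oldest first, including the current epoch).
#' @param current_lr current learning rate.
#' @param cfg a \code{\link{train_config}}.
#' @param last_decay_epoch epoch index (into \code{ema_history}) of the most
#'   recent decay, or 0 if none.
#' @return list with \code{lr} (possibly decayed) and \code{decayed} flag.
#' @export
lr_schedule_step <- function(ema_history, current_lr, cfg,
                             last_decay_epoch = 0L) {
  n <- length(ema_history)
  pat <- cfg$lr_patience_epochs
  if (n <= pat) return(list(lr = current_lr, decayed = FALSE))
  if (n - last_decay_epoch <= pat) return(list(lr = current_lr, decayed = FALSE))
  window <- ema_history[(n - pat + 1L):n]
  before <- ema_history[seq_len(n - pat)]
  if (min(window) > min(before) - cfg$lr_min_improvement)
    list(lr = current_lr / cfg$lr_decay_factor, decayed = TRUE)
  else
    list(lr = current_lr, decayed = FALSE)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# deterministic per-epoch RNG seed: resuming a run mid-stage replays the
# identical batch sequence
epoch_seed <- function(seed, stage, epoch) {
  as.integer((as.numeric(seed) * 48271 + stage * 1299709 + epoch * 7907) %%
               2147483647)
}

# supervision pyramid (targets + predictions) and per-level Md masks for one
# subject under the current network; returns caches for the backward pass
forward_pyramid <- function(network, subj, cfg_loss, want_cache = TRUE) {
  fwd <- net_forward(network, subj$image, want_cache = want_cache)
  targets <- subj$target_pyr    # precomputed at dataset load
  pyr <- vector("list", cfg_loss$dn)
  for (j in seq_len(cfg_loss$dn)) {
    f <- fwd$outputs[[j]]
    pyr[[j]] <- list(target = array(targets[[j]]$x, c(targets[[j]]$dims,
                                                      ncol(targets[[j]]$x))),
                     pred = array(f$x, c(f$dims, ncol(f$x))))
  }
  list(pyramid = pyr, fwd = fwd)
}

prepare_subject <- function(subj, dn) {
  subj$onehot <- one_hot(subj$labels)
  subj$target_pyr <- target_pyramid(subj$onehot, dn)
  subj
}

masks_for_subject <- function(network, subj, loss_cfg) {
  pred <- predict_labels(network, subj$image)
  mr <- extract_misseg(subj$labels, pred, factor = loss_cfg$dilation)
  pool_mask_pyramid(mr$merged, loss_cfg$dn)
}

# light-weight per-epoch monitoring: per-label Dice and raw disagreement
# count (no HD95, which is reserved for final evaluation)
monitor_stats <- function(network, subjects) {
  n <- subjects[[1]]$labels$n_labels
  per <- matrix(0, nrow = length(subjects), ncol = n)
  mis <- 0
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    pred <- predict_labels(network, s$image)
    g <- s$labels$data; p <- pred$data
    per[si, ] <- vapply(0:(n - 1L), function(l) {
      sg <- sum(g == l); sp <- sum(p == l)
      if (sg + sp == 0) 1 else 2 * sum(g == l & p == l) / (sg + sp)
    }, numeric(1))
    mis <- mis + sum(g != p)
  }
  lab_means <- colMeans(per)
  list(mean_dice = mean(rowMeans(per)), misseg_voxels = mis,
       per_label = paste(sprintf("%.4f", lab_means), collapse = ";"))
}

# core epoch loop shared by both stages. mode: "global", "msf" or "total".
run_epochs <- function(network, dataset, cfg, loss_cfg, stage, mode,
                       epochs, log = NULL, adam = NULL, lr = NULL,
                       monitor = NULL, epoch_offset = 0L) {
  if (length(dataset) == 0L) stop("dataset is empty")
  dataset <- lapply(dataset, prepare_subject, dn = loss_cfg$dn)
  if (is.null(adam)) adam <- adam_init(network$params)
  if (is.null(lr)) lr <- cfg$lr_init
  ema <- if (!is.null(log) && nrow(log) > 0) tail(log$ema_loss, 1) else NA_real_
  ema_hist <- numeric(0)
  last_decay <- 0L
  if (is.null(monitor)) monitor <- dataset[seq_len(min(cfg$monitor_subjects,
                                                       length(dataset)))]
  rows <- list()
  for (ep in seq_len(epochs)) {
    set.seed(epoch_seed(cfg$seed, stage, epoch_offset + ep))
    epoch_loss <- 0
    cached_masks <- NULL
    if (mode != "global" && cfg$mask_refresh == "per_epoch") {
      cached_masks <- lapply(dataset, function(s)
        masks_for_subject(network, s, loss_cfg))
    }
    for (bt in seq_len(cfg$batches_per_epoch)) {
      idx <- sample.int(length(dataset), cfg$batch_size, replace = TRUE)
      grads_sum <- NULL
      loss_sum <- 0
      for (i in idx) {
        s <- dataset[[i]]
        fp <- forward_pyramid(network, s, loss_cfg)
        regions <- NULL
        if (mode != "global") {
          regions <- if (!is.null(cached_masks)) cached_masks[[i]]
          else {
            # per-batch refresh: the freshly computed full-resolution output
            # is the current prediction, so the masks are derived from it
            # directly (argmax decode, extract, dilate, merge, pool)
            out1 <- fp$pyramid[[1L]]$pred
            pred <- argmax_labels(out1)
            mr <- extract_misseg(s$labels, pred, factor = loss_cfg$dilation)
            pool_mask_pyramid(mr$merged, loss_cfg$dn)
          }
        }
        loss_sum <- loss_sum +
          objective_value(fp$pyramid, loss_cfg, mode, regions)
        gl <- objective_grad(fp$pyramid, loss_cfg, mode, regions)
        gheads <- lapply(gl, function(g)
          matrix(g, nrow = prod(dim(g)[1:3]), ncol = dim(g)[4]))
        gr <- net_backward(network, fp$fwd$cache, gheads)
        grads_sum <- if (is.null(grads_sum)) gr
                     else Map(`+`, grads_sum, gr)
      }
      grads <- lapply(grads_sum, function(g) g / cfg$batch_size)
      st <- adam_step(network$params, grads, adam, lr)
      network$params <- st$params
      adam <- st$state
      epoch_loss <- epoch_loss + loss_sum / cfg$batch_size
    }
    epoch_loss <- epoch_loss / cfg$batches_per_epoch
    ema <- if (is.na(ema)) epoch_loss
           else cfg$ema_alpha * ema + (1 - cfg$ema_alpha) * epoch_loss
    ema_hist <- c(ema_hist, ema)
    dec <- lr_schedule_step(ema_hist, lr, cfg, last_decay)
    if (dec$decayed) last_decay <- length(ema_hist)
    lr_this <- lr
    lr <- dec$lr
    ms <- monitor_stats(network, monitor)
    rows[[ep]] <- data.frame(stage = stage, epoch = epoch_offset + ep,
                             lr = lr_this, loss = epoch_loss, ema_loss = ema,
                             val_dice = ms$mean_dice,
                             val_dice_per_label = ms$per_label,
                             misseg_voxels = ms$misseg_voxels)
  }
  newlog <- do.call(rbind, c(list(log), rows))
  if (is.null(newlog))
    newlog <- data.frame(stage = integer(0), epoch = integer(0),
                         lr = numeric(0), loss = numeric(0),
                         ema_loss = numeric(0), val_dice = numeric(0),
                         val_dice_per_label = character(0),
                         misseg_voxels = numeric(0))
  list(network = network, log = newlog, adam = adam, lr = lr)
}

#' Stage-1 training (global loss)
#'
#' Coarse training of the network with the deep-supervised global Dice + CE
#' objective and Adam, applying the EMA learning-rate decay rule each epoch
#' and logging loss, EMA loss, monitoring-subset Dice and mis-seg voxel
#' counts.
#'
#' @param network an \code{msf_network} (see \code{\link{build_network}}).
#' @param dataset list of subjects, each a list with \code{image} (3D array)
#'   and \code{labels} (a \code{\link{label_volume}}).
#' @param cfg a \code{\link{train_config}}.
#' @param loss_cfg a \code{\link{loss_config}} (its \code{dn} must match the
#'   network's).
#' @return list with \code{network} (trained), \code{log} (one data.frame row
#'   per epoch), \code{adam} (optimizer state) and \code{lr}.
#' @export
train_stage1 <- function(network, dataset, cfg = train_config(),
                         loss_cfg = loss_config(dn = network$cfg$dn)) {
  run_epochs(network, dataset, cfg, loss_cfg, stage = 1L, mode = "global",
             epochs = cfg$stage1_epochs)
}

#' Stage-2 training (global + mis-seg-focused loss)
#'
#' Refines a stage-1 network: per batch (default) or per epoch, the current
#' prediction is argmax-decoded, per-label mis-segmentation regions are
#' extracted, dilated and merged, the merged mask is OR-pooled down the
#' supervision pyramid, and the objective becomes
#' \eqn{L_{Global} + \lambda L_{MSF}}. Masks are constants for the gradient.
#'
#' @inheritParams train_stage1
#' @param state optional list with \code{adam} and \code{lr} from stage 1 to
#'   continue the optimizer/schedule instead of restarting.
#' @param mode training objective for the second stage: \code{"total"}
#'   (default, global + lambda * MSF), \code{"global"} or \code{"msf"}
#'   (ablation schedules).
#' @param log existing training log to append to.
#' @return as \code{\link{train_stage1}}.
#' @export
train_stage2 <- function(network, dataset, cfg = train_config(),
                         loss_cfg = loss_config(dn = network$cfg$dn),
                         state = NULL, mode = "total", log = NULL) {
  lr <- if (!is.null(state) && !cfg$lr_reset_stage2) state$lr else NULL
  adam <- if (!is.null(state)) state$adam else NULL
  run_epochs(network, dataset, cfg, loss_cfg, stage = 2L, mode = mode,
             epochs = cfg$stage2_epochs, log = log, adam = adam, lr = lr)
}
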