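#' Loss configuration
#'
#' Bundles the tunable parameters of the compound segmentation loss.
#'
#' @param omega non-negative weight of the cross-entropy term inside the
#'   compound loss (default 1: Dice and CE contribute equally).
#' @param lambda non-negative weight of the mis-seg-focused term added in
#'   stage 2 (default 1, the ablation optimum).
#' @param dn number of deep-supervision levels (default 3: the three
#'   highest-resolution decoder outputs).
#' @param dilation dilation factor used when building error masks (default 2).
#' @param eps numerical floor for the Dice denominator and CE log clipping.
#' @param channel_mean if TRUE, Dice/CE are averaged per channel instead of
#'   pooled over channels and voxels jointly (default FALSE: one global ratio).
#' @return list of class \code{loss_config}.
#' @export
loss_config <- function(omega = 1.0, lambda = 1.0, dn = 3L, dilation = 2L,
                        eps = 1e-7, channel_mean = FALSE) {
  omega <- as.numeric(omega)
  lambda <- as.numeric(lambda)
  eps <- as.numeric(eps)
  stopifnot(omega >= 0, lambda >= 0, dn >= 1, dilation >= 0, eps > 0)
  structure(list(omega = omega, lambda = lambda, dn = as.integer(dn),
                 ds_weights = ds_weights(dn), dilation = as.integer(dilation),
                 eps = eps, channel_mean = isTRUE(channel_mean)),
            class = "loss_config")
}

#' Deep-supervision level weights
#'
#' Weight of supervision level j (j = 1 is the full-resolution decoder
#' output): \eqn{a_j = 2^{-(j-1)} / \sum_{k=1}^{dn} 2^{-(k-1)}}. Each coarser
#' level gets exactly half the weight of the previous one, and the weights
#' sum to 1.
#'
#' @param dn positive integer, number of supervision levels.
#' @return numeric vector of length \code{dn} summing to 1.
#' @examples
#' ds_weights(3)  # 4/7, 2/7, 1/7
#' @export
ds_weights <- function(dn) {
  if (length(dn) != 1L || is.na(dn) || dn < 1 || dn != round(dn))
    stop("dn must be a positive integer")
  w <- 2^(-(seq_len(dn) - 1))
  w / sum(w)
}

check_stack_pair <- function(target, pred) {
  if (!identical(dim(target), dim(pred)))
    stop("target and pred must have identical shapes")
}

#' Soft Dice loss
#'
#' \eqn{-2\sum t_i p_i / (\sum t_i + \sum p_i + \epsilon)}, summed jointly
#' over all voxels and channels (one global ratio). The sign convention makes
#' -1 a perfect match and 0 total disagreement. When both stacks are
#' identically zero the loss is defined as 0.
#'
#' @param target,pred arrays of the same shape with values in [0, 1].
#' @param eps stabilising constant added to the denominator.
#' @param channel_mean average the per-channel Dice losses of a 4D stack
#'   instead of pooling (default FALSE).
#' @return scalar in [-1, 0].
#' @export
dice_loss <- function(target, pred, eps = 1e-7, channel_mean = FALSE) {
  check_stack_pair(target, pred)
  if (channel_mean && length(dim(target)) == 4L) {
    n <- dim(target)[4]
    v <- vapply(seq_len(n), function(i)
      dice_loss(target[, , , i, drop = FALSE], pred[, , , i, drop = FALSE],
                eps = eps), numeric(1))
    return(mean(v))
  }
  st <- sum(target); sp <- sum(pred)
  if (st == 0 && sp == 0) return(0)
  -2 * sum(target * pred) / (st + sp + eps)
}

# gradient of dice_loss w.r.t. pred (pooled variant used in training)
dice_loss_grad <- function(target, pred, eps = 1e-7) {
  st <- sum(target); sp <- sum(pred)
  if (st == 0 && sp == 0) return(array(0, dim = dim(pred)))
  den <- st + sp + eps
  num <- sum(target * pred)
  -2 * target / den + 2 * num / den^2
}

#' Binary cross-entropy loss
#'
#' Per-element binary cross-entropy, averaged over all voxels and channels:
#' \eqn{-\frac{1}{M}\sum_i [t_i \log p_i + (1-t_i)\log(1-p_i)]}. Predictions
#' are clipped to \eqn{[\epsilon, 1-\epsilon]} before the logs so the loss is
#' always finite.
#'
#' @param target array with values in \{0, 1\}.
#' @param pred array of the same shape with values in [0, 1].
#' @param eps clipping constant.
#' @param channel_mean average per-channel CE of a 4D stack (default FALSE;
#'   for this per-element form the pooled and channel-mean variants agree
#'   whenever channels have equal size).
#' @return non-negative scalar.
#' @export
ce_loss <- function(target, pred, eps = 1e-7, channel_mean = FALSE) {
  check_stack_pair(target, pred)
  if (!all(target == 0 | target == 1))
    stop("ce_loss target values must be 0 or 1")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# gradient of ce_loss w.r.t. pred
ce_loss_grad <- function(target, pred, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  g <- -(target / p - (1 - target) / (1 - p)) / length(target)
  array(g, dim = dim(pred))
}

check_pyramid <- function(pyramid, dn) {
  if (!is.list(pyramid) || length(pyramid) != dn)
    stop("pyramid must have exactly dn = ", dn, " levels, got ", length(pyramid))
  for (lv in pyramid) {
    if (is.null(lv$target) || is.null(lv$pred))
      stop("each pyramid level needs $target and $pred stacks")
    check_stack_pair(lv$target, lv$pred)
  }
}

#' Deep-supervised compound Dice + CE loss
#'
#' \eqn{\sum_{j=1}^{dn} a_j [L_{Dice}(t_j, p_j) + \omega L_{CE}(t_j, p_j)]},
#' where level j = 1 is the full-resolution output and \eqn{a_j} are the
#' geometric deep-supervision weights of \code{\link{ds_weights}}.
#'
#' @param pyramid list of \code{dn} levels, each a list with \code{target}
#'   and \code{pred} channel stacks at that level's resolution.
#' @param cfg a \code{\link{loss_config}}.
#' @return scalar loss.
#' @export
compound_loss <- function(pyramid, cfg = loss_config()) {
  check_pyramid(pyramid, cfg$dn)
  a <- cfg$ds_weights
  total <- 0
  for (j in seq_len(cfg$dn)) {
    lv <- pyramid[[j]]
    total <- total + a[j] *
      (dice_loss(lv$target, lv$pred, cfg$eps, cfg$channel_mean) +
         cfg$omega * ce_loss(lv$target, lv$pred, cfg$eps, cfg$channel_mean))
  }
  total
}

#' Global segmentation loss
#'
#' The compound deep-supervised loss evaluated over the whole volume: the
#' stage-1 training objective.
#'
#' @inheritParams compound_loss
#' @return scalar loss.
#' @export
global_loss <- function(pyramid, cfg = loss_config()) {
  compound_loss(pyramid, cfg)
}

#' Mis-seg-focused (MSF) loss
#'
#' Masks both target and prediction of every supervision level by that
#' level's binary error region (voxels outside the region become exactly
#' zero), then evaluates the compound loss. With all-ones masks it equals
#' \code{\link{global_loss}}; with all-empty masks it is exactly 0.
#'
#' @inheritParams compound_loss
#' @param regions_per_level list of \code{dn} binary 3D masks, one per level
#'   at that level's spatial resolution.
#' @return scalar loss.
#' @export
msf_loss <- function(pyramid, regions_per_level, cfg = loss_config()) {
  check_pyramid(pyramid, cfg$dn)
  if (length(regions_per_level) != cfg$dn)
    stop("need one region mask per supervision level")
  if (all(vapply(regions_per_level, function(m) sum(m) == 0, logical(1))))
    return(0)
  masked <- vector("list", cfg$dn)
  for (j in seq_len(cfg$dn)) {
    lv <- pyramid[[j]]
    md <- regions_per_level[[j]]
    if (!identical(dim(md), dim(lv$target)[1:3]))
      stop("region mask shape does not match level ", j)
    masked[[j]] <- list(target = mask_by_region(md, lv$target),
                        pred = mask_by_region(md, lv$pred))
  }
  compound_loss(masked, cfg)
}

#' Two-stage training objective
#'
#' Stage 1 is the global loss alone; stage 2 adds the mis-seg-focused term
#' with weight \eqn{\lambda}: \eqn{L_2 = L_{Global} + \lambda L_{MSF}}.
#'
#' @inheritParams msf_loss
#' @param stage 1 or 2.
#' @return scalar loss.
#' @export
stage_loss <- function(stage, pyramid, regions_per_level = NULL,
                       cfg = loss_config()) {
  if (!(length(stage) == 1L && stage %in% c(1, 2)))
    stop("stage must be 1 or 2")
  g <- global_loss(pyramid, cfg)
  if (stage == 1) return(g)
  if (is.null(regions_per_level))
    stop("stage 2 requires regions_per_level")
  g + cfg$lambda * msf_loss(pyramid, regions_per_level, cfg)
}

# Gradient of the training objective w.r.t. each level's prediction stack.
# mode: "global", "msf", or "total" (global + lambda*msf). Masks are treated
# as constants: no gradient flows through region construction.
objective_grad <- function(pyramid, cfg, mode = "global",
                           regions_per_level = NULL) {
  a <- cfg$ds_weights
  grads <- vector("list", cfg$dn)
  for (j in seq_len(cfg$dn)) {
    lv <- pyramid[[j]]
    g <- array(0, dim = dim(lv$pred))
    if (mode %in% c("global", "total")) {
      g <- g + dice_loss_grad(lv$target, lv$pred, cfg$eps) +
        cfg$omega * ce_loss_grad(lv$target, lv$pred, cfg$eps)
    }
    if (mode %in% c("msf", "total") && !is.null(regions_per_level)) {
      md <- regions_per_level[[j]]
      if (sum(md) > 0) {
        tm <- mask_by_region(md, lv$target)
        pm <- mask_by_region(md, lv$pred)
        gm <- dice_loss_grad(tm, pm, cfg$eps) +
          cfg$omega * ce_loss_grad(tm, pm, cfg$eps)
        gm <- mask_by_region(md, gm)  # chain rule through the constant mask
        g <- g + (if (mode == "total") cfg$lambda else 1) * gm
      }
    }
    grads[[j]] <- a[j] * g
  }
  grads
}

# objective value matching objective_grad (used by the trainer / presets)
objective_value <- function(pyramid, cfg, mode = "global",
                            regions_per_level = NULL) {
  switch(mode,
    global = global_loss(pyramid, cfg),
    msf = msf_loss(pyramid, regions_per_level, cfg),
    total = stage_loss(2, pyramid, regions_per_level, cfg),
    stop("unknown objective mode: ", mode))
}
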