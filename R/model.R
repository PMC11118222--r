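#' Fit a two-stage mis-seg-focused segmentation model
#'
#' The package's main fitting function. Builds (or continues) a network,
#' runs the requested stage schedule, and returns a classed model with the
#' usual methods (\code{print}, \code{summary}, \code{predict}, \code{plot},
#' \code{coef}).
#'
#' Schedules mirror the stage ablation:
#' \describe{
#'   \item{\code{"global_only"}}{stage 1 only (global loss); stage 2 skipped.}
#'   \item{\code{"global_global"}}{stage 2 continues with the global loss
#'     (matched-epochs control).}
#'   \item{\code{"global_msf"}}{stage 2 uses only the mis-seg-focused loss.}
#'   \item{\code{"total_total"}}{both stages use global + lambda * MSF
#'     (cold-start MSF).}
#'   \item{\code{"global_then_total"}}{the recommended schedule: global loss
#'     in stage 1, global + lambda * MSF in stage 2.}
#' }
#'
#' @param data list of training subjects, each a list with \code{image}
#'   (3D array) and \code{labels} (\code{\link{label_volume}}).
#' @param schedule one of the five schedule names above.
#' @param network a \code{\link{network_config}} or an existing
#'   \code{msf_network} to continue training.
#' @param loss a \code{\link{loss_config}}.
#' @param train a \code{\link{train_config}}.
#' @param seed overrides \code{train$seed} when given; governs weight
#'   initialisation and batch sampling.
#' @return object of class \code{msf_model}: list with \code{network},
#'   \code{log} (per-epoch data.frame), \code{schedule}, \code{configs} and
#'   \code{state} (optimizer state + lr, for resuming).
#' @examples
#' \donttest{
#' set.seed(1)
#' subs <- lapply(1:3, function(i)
#'   generate_phantom(phantom_spec(seed = i))[c("image", "labels")])
#' cfg <- train_config(stage1_epochs = 2, stage2_epochs = 1,
#'                     batches_per_epoch = 2)
#' fit <- msf_train(subs, train = cfg)
#' print(fit)
#' }
#' @export
msf_train <- function(data, schedule = "global_then_total",
                      network = network_preset("desk",
                        n_labels = data[[1]]$labels$n_labels),
                      loss = NULL, train = train_config(), seed = NULL) {
  schedules <- list(
    global_only       = list(s1 = "global", s2 = NULL),
    global_global     = list(s1 = "global", s2 = "global"),
    global_msf        = list(s1 = "global", s2 = "msf"),
    total_total       = list(s1 = "total",  s2 = "total"),
    global_then_total = list(s1 = "global", s2 = "total"))
  if (!schedule %in% names(schedules))
    stop("unknown schedule: ", schedule, " (expected one of ",
         paste(names(schedules), collapse = ", "), ")")
  sch <- schedules[[schedule]]
  if (!is.null(seed)) train$seed <- as.integer(seed)
  if (inherits(network, "network_config")) {
    set.seed(train$seed)
    network <- build_network(network)
  }
  if (is.null(loss)) loss <- loss_config(dn = network$cfg$dn)
  if (loss$dn != network$cfg$dn)
    stop("loss dn (", loss$dn, ") must match network dn (", network$cfg$dn, ")")
  r1 <- run_epochs(network, data, train, loss, stage = 1L, mode = sch$s1,
                   epochs = train$stage1_epochs)
  net <- r1$network; log <- r1$log; state <- list(adam = r1$adam, lr = r1$lr)
  if (!is.null(sch$s2) && train$stage2_epochs > 0) {
    r2 <- train_stage2(net, data, train, loss,
                       state = state, mode = sch$s2, log = log)
    net <- r2$network; log <- r2$log; state <- list(adam = r2$adam, lr = r2$lr)
  }
  structure(list(network = net, log = log, schedule = schedule,
                 configs = list(loss = loss, train = train,
                                network = net$cfg),
                 state = state),
            class = "msf_model")
}

#' Run a stage-schedule experiment on seeded phantoms
#'
#' Generates a phantom dataset, fits one of the five stage schedules, and
#' evaluates Dice / HD95 / mis-seg voxel counts on the held-out test
#' phantoms. Presets correspond to the stage-ablation rows; all share the
#' stage-1 trajectory when their schedules coincide and the same seed is
#' used.
#'
#' @param preset schedule name, see \code{\link{msf_train}}.
#' @param seed global seed for phantoms, initialisation and batches.
#' @param n_subjects number of phantoms (split 4:1 train:test).
#' @param spec a \code{\link{phantom_spec}} (its seed is replaced by
#'   \code{seed}).
#' @param network,loss,train configuration overrides.
#' @return list with \code{model} (\code{msf_model}), \code{test_eval}
#'   (per-subject \code{eval_report}s), \code{test_mean_dice},
#'   \code{test_mean_hd95}, \code{test_misseg_voxels} and \code{metrics}
#'   (per-subject data.frame).
#' @export
run_experiment <- function(preset = "global_then_total", seed = 1L,
                           n_subjects = 25L, spec = phantom_spec(),
                           network = NULL, loss = NULL,
                           train = train_config()) {
  spec$seed <- as.integer(seed)
  seeds <- subject_seeds(spec$seed, n_subjects)
  subs <- lapply(seeds, function(s) {
    sp <- spec; sp$seed <- s
    generate_phantom(sp)[c("image", "labels")]
  })
  n_test <- max(1L, round(n_subjects / 5))
  test_idx <- seq(n_subjects - n_test + 1L, n_subjects)
  train_set <- subs[-test_idx]
  test_set <- subs[test_idx]
  if (is.null(network))
    network <- network_preset("desk", n_labels = spec$n_labels + spec$n_inserts)
  fit <- msf_train(train_set, schedule = preset, network = network,
                   loss = loss, train = train, seed = seed)
  evs <- lapply(test_set, function(s)
    evaluate(s$labels, predict_labels(fit$network, s$image,
                                      spacing = s$labels$spacing)))
  metrics <- data.frame(
    subject = seq_along(evs),
    mean_dice = vapply(evs, function(e) e$mean_dice, numeric(1)),
    mean_hd95 = vapply(evs, function(e) e$mean_hd95, numeric(1)),
    misseg_voxels = vapply(evs, function(e) e$misseg_voxels, numeric(1)))
  list(model = fit, test_eval = evs,
       test_mean_dice = mean(metrics$mean_dice),
       test_mean_hd95 = mean(metrics$mean_hd95, na.rm = TRUE),
       test_misseg_voxels = sum(metrics$misseg_voxels),
       metrics = metrics)
}

#' @export
print.msf_model <- function(x, ...) {
  cat(sprintf("<msf_model> schedule '%s', %d epochs trained\n",
              x$schedule, nrow(x$log)))
  print(x$network)
  if (nrow(x$log) > 0) {
    last <- tail(x$log, 1)
    cat(sprintf("  final: stage %d epoch %d | loss %.4f | EMA %.4f | monitor Dice %.4f | mis-seg %d\n",
                last$stage, last$epoch, last$loss, last$ema_loss,
                last$val_dice, last$misseg_voxels))
  }
  invisible(x)
}

#' @export
summary.msf_model <- function(object, ...) {
  log <- object$log
  by_stage <- split(log, log$stage)
  cat(sprintf("Two-stage mis-seg-focused segmentation model ('%s')\n",
              object$schedule))
  for (s in names(by_stage)) {
    l <- by_stage[[s]]
    cat(sprintf("  stage %s: %d epochs | loss %.4f -> %.4f | monitor Dice %.4f -> %.4f | mis-seg %d -> %d\n",
                s, nrow(l), l$loss[1], tail(l$loss, 1),
                l$val_dice[1], tail(l$val_dice, 1),
                l$misseg_voxels[1], tail(l$misseg_voxels, 1)))
  }
  cat(sprintf("  lambda %.3g | omega %.3g | dilation %d | dn %d | lr decays: %d\n",
              object$configs$loss$lambda, object$configs$loss$omega,
              object$configs$loss$dilation, object$configs$loss$dn,
              sum(diff(log$lr) < 0)))
  invisible(object)
}

#' @export
predict.msf_model <- function(object, newdata, spacing = c(1, 1, 1), ...) {
  if (is.list(newdata) && !is.array(newdata))
    return(lapply(newdata, function(im) predict_labels(object$network, im, spacing)))
  predict_labels(object$network, newdata, spacing)
}

#' @export
coef.msf_model <- function(object, ...) object$network$params

#' @export
plot.msf_model <- function(x, which = c("loss", "dice", "misseg"), ...) {
  which <- match.arg(which)
  log <- x$log
  s2 <- log$epoch[match(2, log$stage)]
  if (which == "loss") {
    plot(log$epoch, log$loss, type = "l", xlab = "epoch", ylab = "training loss",
         main = "training loss (grey: EMA)", ...)
    lines(log$epoch, log$ema_loss, col = "grey50")
  } else if (which == "dice") {
    plot(log$epoch, log$val_dice, type = "l", xlab = "epoch",
         ylab = "monitoring-subset mean Dice", ...)
  } else {
    plot(log$epoch, log$misseg_voxels, type = "l", xlab = "epoch",
         ylab = "monitoring-subset mis-seg voxels", ...)
  }
  if (!is.na(s2)) abline(v = s2, lty = 2, col = "red")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file embedding the network parameters and
#' every configuration needed to resume training or predict.
#'
#' @param model an \code{msf_model} (or \code{msf_network}).
#' @param path file path.
#' @return \code{load_checkpoint} returns the saved object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Matched two-arm comparison of stage-2 objectives
#'
#' Runs the stage-schedule comparison at phantom scale with matched epochs,
#' seeds and a shared stage-1 trajectory: stage 1 is trained once with the
#' global loss, then two stage-2 arms continue from identical weights and
#' optimizer state -- one with the global + lambda * MSF objective
#' (\code{"global_then_total"}), one with the global loss alone
#' (\code{"global_global"}, the matched-epochs control). Reports test-set
#' mean Dice for both arms and the monitoring mis-seg voxel counts at the
#' two stage boundaries.
#'
#' @param seed integer seed for phantoms, initialisation and batches.
#' @param n_subjects phantoms to generate (4:1 train:test split).
#' @param spec phantom specification.
#' @param network a \code{\link{network_config}}.
#' @param loss a \code{\link{loss_config}}.
#' @param train a \code{\link{train_config}}.
#' @return list with \code{misseg_stage1}, \code{misseg_stage2} (monitoring
#'   counts at each stage end, MSF arm), \code{dice_msf}, \code{dice_control}
#'   (test mean Dice of the two arms) and \code{logs}.
#' @export
compare_schedules <- function(seed = 1L, n_subjects = 25L,
                              spec = phantom_spec(),
                              network = network_preset("desk",
                                n_labels = spec$n_labels + spec$n_inserts),
                              loss = loss_config(dn = network$dn),
                              train = train_preset("desk", seed = seed)) {
  spec$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  seeds <- subject_seeds(spec$seed, n_subjects)
  subs <- lapply(seeds, function(s) {
    sp <- spec; sp$seed <- s
    generate_phantom(sp)[c("image", "labels")]
  })
  n_test <- max(1L, round(n_subjects / 5))
  test_idx <- seq(n_subjects - n_test + 1L, n_subjects)
  train_set <- subs[-test_idx]
  test_set <- subs[test_idx]
  set.seed(train$seed)
  net <- build_network(network)
  r1 <- train_stage1(net, train_set, train, loss)
  st <- list(adam = r1$adam, lr = r1$lr)
  arms <- lapply(c(total = "total", global = "global"), function(m)
    train_stage2(r1$network, train_set, train, loss, state = st, mode = m,
                 log = r1$log))
  test_dice <- function(nn) mean(vapply(test_set, function(s)
    evaluate(s$labels, predict_labels(nn, s$image))$mean_dice, numeric(1)))
  list(misseg_stage1 = tail(r1$log$misseg_voxels, 1),
       misseg_stage2 = tail(arms$total$log$misseg_voxels, 1),
       dice_msf = test_dice(arms$total$network),
       dice_control = test_dice(arms$global$network),
       logs = list(stage1 = r1$log, msf = arms$total$log,
                   control = arms$global$log))
}
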