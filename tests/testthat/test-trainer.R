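lr_cfg <- train_config(lr_patience_epochs = 30L, lr_min_improvement = 5e-3,
                       lr_decay_factor = 5)

apply_schedule <- function(ema, lr0, cfg) {
  lr <- lr0
  last <- 0L
  decays <- integer(0)
  for (n in seq_along(ema)) {
    r <- lr_schedule_step(ema[1:n], lr, cfg, last)
    if (r$decayed) { last <- n; decays <- c(decays, n) }
    lr <- r$lr
  }
  list(lr = lr, decays = decays)
}

test_that("learning rate holds while the EMA keeps improving", {
  ema <- 1 - 0.01 * (1:60)    # drops 0.01 per epoch, above the 5e-3 threshold
  r <- apply_schedule(ema, 3e-4, lr_cfg)
  expect_equal(r$lr, 3e-4)
  expect_length(r$decays, 0)
})

test_that("a flat EMA for a full window triggers exactly one factor-5 decay", {
  ema <- c(rep(1, 31))        # flat for patience + 1 epochs
  r <- apply_schedule(ema, 3e-4, lr_cfg)
  expect_equal(r$lr, 3e-4 / 5)
  expect_equal(r$decays, 31L)

  # cool-down: continuing flat cannot decay again within one window
  ema2 <- rep(1, 45)
  r2 <- apply_schedule(ema2, 3e-4, lr_cfg)
  expect_equal(r2$lr, 3e-4 / 5)
  # but after a full second window it decays again
  ema3 <- rep(1, 62)
  r3 <- apply_schedule(ema3, 3e-4, lr_cfg)
  expect_equal(r3$lr, 3e-4 / 25)
})

test_that("plateau-then-drop sequences decay exactly where the oracle says", {
  set.seed(8)
  for (trial in 1:10) {
    # synthetic EMA: improving runs interleaved with plateaus
    ema <- cumsum(c(1, ifelse(runif(79) < 0.4, -0.02, 0)))
    r <- apply_schedule(ema, 1e-3, lr_cfg)
    o <- oracle_lr_walk(ema, 1e-3)
    expect_identical(r$decays, as.integer(o$decays))
    expect_equal(r$lr, o$lr)
  }
})

test_that("stage-1 no-op schedule leaves the network unchanged", {
  subs <- small_training_set(2, seed = 20, shape = c(16, 16, 16))
  cfg <- train_config(stage1_epochs = 0, seed = 1)
  set.seed(1)
  net <- build_network(network_config(4, base_filters = 2, n_down = 2, dn = 2))
  r <- train_stage1(net, subs, cfg, loss_config(dn = 2))
  expect_identical(r$network$params, net$params)
  expect_equal(nrow(r$log), 0)
  expect_error(train_stage1(net, list(), cfg), "empty")
})

test_that("identical seeds reproduce identical loss sequences", {
  subs <- small_training_set(3, seed = 30, shape = c(16, 16, 16))
  cfg <- train_preset("desk", stage1_epochs = 3, stage2_epochs = 2,
                      batches_per_epoch = 3, seed = 9, monitor_subjects = 2)
  run <- function() {
    msf_train(subs, schedule = "global_then_total",
              network = network_config(4, base_filters = 2, n_down = 2, dn = 2),
              loss = loss_config(dn = 2), train = cfg)
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$log$ema_loss, m2$log$ema_loss)
  expect_identical(m1$log$misseg_voxels, m2$log$misseg_voxels)
})

test_that("stage 2 with lambda 0 replays the global-objective dynamics", {
  subs <- small_training_set(2, seed = 40, shape = c(16, 16, 16))
  cfg <- train_preset("desk", stage1_epochs = 2, stage2_epochs = 3,
                      batches_per_epoch = 3, seed = 4, monitor_subjects = 1)
  set.seed(4)
  net <- build_network(network_config(4, base_filters = 2, n_down = 2, dn = 2))
  r1 <- train_stage1(net, subs, cfg, loss_config(dn = 2))
  st <- list(adam = r1$adam, lr = r1$lr)
  a <- train_stage2(r1$network, subs, cfg, loss_config(dn = 2, lambda = 0),
                    state = st, mode = "total")
  b <- train_stage2(r1$network, subs, cfg, loss_config(dn = 2),
                    state = st, mode = "global")
  # lambda = 0 degeneracy: identical losses and identical final weights
  expect_equal(a$log$loss, b$log$loss, tolerance = 1e-12)
  expect_equal(a$network$params, b$network$params, tolerance = 1e-10)
})

test_that("stage-2 objective exceeds the stage-1 objective by lambda * MSF", {
  subs <- small_training_set(1, seed = 50, shape = c(16, 16, 16))
  lc <- loss_config(dn = 2, lambda = 1)
  set.seed(5)
  net <- build_network(network_config(4, base_filters = 2, n_down = 2, dn = 2))
  s <- msfseg:::prepare_subject(subs[[1]], 2)
  fp <- msfseg:::forward_pyramid(net, s, lc)
  pred <- argmax_labels(fp$pyramid[[1]]$pred)
  mr <- extract_misseg(s$labels, pred, factor = lc$dilation)
  masks <- msfseg:::pool_mask_pyramid(mr$merged, lc$dn)
  s1 <- stage_loss(1, fp$pyramid, cfg = lc)
  s2 <- stage_loss(2, fp$pyramid, masks, lc)
  lm <- msf_loss(fp$pyramid, masks, lc)
  expect_equal(s2 - s1, lc$lambda * lm, tolerance = 1e-12)
  if (lm >= 0) expect_gte(s2, s1)
})

test_that("checkpoint resume reproduces the uninterrupted run", {
  subs <- small_training_set(2, seed = 60, shape = c(16, 16, 16))
  netcfg <- network_config(4, base_filters = 2, n_down = 2, dn = 2)
  lc <- loss_config(dn = 2)
  cfg6 <- train_config(stage1_epochs = 6, batches_per_epoch = 3, seed = 11,
                       monitor_subjects = 1)
  set.seed(11)
  full <- train_stage1(build_network(netcfg), subs, cfg6, lc)

  cfg3 <- train_config(stage1_epochs = 3, batches_per_epoch = 3, seed = 11,
                       monitor_subjects = 1)
  set.seed(11)
  half <- train_stage1(build_network(netcfg), subs, cfg3, lc)
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  save_checkpoint(list(network = half$network, adam = half$adam, lr = half$lr,
                       log = half$log), f)
  ck <- load_checkpoint(f)
  resumed <- msfseg:::run_epochs(ck$network, subs, cfg3, lc, stage = 1L,
                                 mode = "global", epochs = 3, log = ck$log,
                                 adam = ck$adam, lr = ck$lr, epoch_offset = 3L)
  expect_equal(resumed$log$loss, full$log$loss, tolerance = 1e-12)
})

test_that("learning rate is non-increasing and positive over a run", {
  subs <- small_training_set(2, seed = 70, shape = c(16, 16, 16))
  cfg <- train_preset("desk", stage1_epochs = 5, stage2_epochs = 0,
                      batches_per_epoch = 2, seed = 2, monitor_subjects = 1,
                      lr_patience_epochs = 2, lr_min_improvement = 10)
  # absurd improvement threshold forces decays: lr must only ever shrink
  set.seed(2)
  net <- build_network(network_config(4, base_filters = 2, n_down = 2, dn = 2))
  r <- train_stage1(net, subs, cfg, loss_config(dn = 2))
  expect_true(all(diff(r$log$lr) <= 0))
  expect_true(all(r$log$lr > 0))
})

test_that("run_experiment presets share the stage-1 trajectory", {
  tr <- train_preset("desk", stage1_epochs = 2, stage2_epochs = 2,
                     batches_per_epoch = 2, seed = 3, monitor_subjects = 1)
  spec <- phantom_spec(shape = c(16, 16, 16))
  nc <- network_config(4, base_filters = 2, n_down = 2, dn = 2)
  lc <- loss_config(dn = 2)
  logs <- lapply(c("global_only", "global_global", "global_then_total"),
                 function(p) run_experiment(p, seed = 3, n_subjects = 5,
                                            spec = spec, network = nc,
                                            loss = lc, train = tr)$model$log)
  s1 <- lapply(logs, function(l) l$loss[l$stage == 1])
  expect_identical(s1[[1]], s1[[2]])
  expect_identical(s1[[1]], s1[[3]])
  expect_error(run_experiment("nope", seed = 1, n_subjects = 2, spec = spec,
                              network = nc, loss = lc, train = tr), "schedule")
})
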