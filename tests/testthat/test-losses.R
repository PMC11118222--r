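test_that("deep-supervision weights follow the geometric rule", {
  expect_identical(ds_weights(1), 1)
  expect_equal(ds_weights(3), c(4 / 7, 2 / 7, 1 / 7))
  for (dn in 1:8) {
    w <- ds_weights(dn)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w[1], 2^(dn - 1) / (2^dn - 1))
    if (dn > 1) expect_equal(w[-dn] / w[-1], rep(2, dn - 1))
  }
  expect_error(ds_weights(0), "positive")
})

test_that("dice_loss closed forms and oracle agreement", {
  ones <- array(1, dim = c(3, 3, 3, 2))
  expect_equal(dice_loss(ones, ones), -1, tolerance = 1e-6)

  # disjoint support: zero numerator
  a <- array(0, dim = c(2, 2, 2)); a[1, 1, 1] <- 1
  b <- array(0, dim = c(2, 2, 2)); b[2, 2, 2] <- 1
  expect_equal(dice_loss(a, b), 0)

  # both empty is defined as 0
  z <- array(0, dim = c(2, 2, 2))
  expect_equal(dice_loss(z, z), 0)

  for (seed in 1:10) {
    set.seed(seed)
    t <- array(runif(4^3 * 3), dim = c(4, 4, 4, 3))
    p <- array(runif(4^3 * 3), dim = c(4, 4, 4, 3))
    expect_equal(dice_loss(t, p), oracle_dice_loss(t, p), tolerance = 1e-12)
    expect_gte(dice_loss(t, p), -1)
    expect_lte(dice_loss(t, p), 0)
    # invariance under a common spatial permutation
    set.seed(seed + 1)
    perm <- sample(64)
    tp <- array(matrix(t, 64, 3)[perm, ], dim = dim(t))
    pp <- array(matrix(p, 64, 3)[perm, ], dim = dim(p))
    expect_equal(dice_loss(tp, pp), dice_loss(t, p), tolerance = 1e-12)
  }
})

test_that("ce_loss closed forms and oracle agreement", {
  t1 <- array(1, dim = c(2, 2, 2))
  p5 <- array(0.5, dim = c(2, 2, 2))
  expect_equal(ce_loss(t1, p5), log(2), tolerance = 1e-6)

  # perfectly confident correct prediction: bounded only by the eps floor
  t <- array(c(0, 1), dim = c(2, 2, 2))
  expect_lt(ce_loss(t, t), 1e-5)

  for (seed in 1:10) {
    set.seed(seed)
    t <- array(rbinom(4^3 * 2, 1, 0.5), dim = c(4, 4, 4, 2))
    p <- array(runif(4^3 * 2, 0.05, 0.95), dim = c(4, 4, 4, 2))
    expect_equal(ce_loss(t, p), oracle_ce_loss(t, p), tolerance = 1e-12)
    expect_gte(ce_loss(t, p), 0)
  }
  expect_error(ce_loss(array(0.5, c(1, 1, 1)), array(0.5, c(1, 1, 1))), "0 or 1")
})

test_that("compound_loss is the weighted per-level sum", {
  cfg1 <- loss_config(omega = 0, dn = 1)
  pyr <- random_pyramid(c(4, 4, 4), 2, 1, seed = 5)
  expect_equal(compound_loss(pyr, cfg1), dice_loss(pyr[[1]]$target, pyr[[1]]$pred))

  # perfect confident predictions at all levels -> -1
  cfg3 <- loss_config(dn = 3)
  d <- c(8, 8, 8)
  perf <- lapply(1:3, function(j) {
    set.seed(j)
    t <- array(rbinom(prod(d) * 2, 1, 0.5), dim = c(d, 2))
    out <- list(target = t, pred = t)
    d <<- d %/% 2L
    out
  })
  expect_equal(compound_loss(perf, cfg3), -1, tolerance = 1e-4)

  cfg2 <- loss_config(dn = 2)
  pyr2 <- random_pyramid(c(4, 4, 4), 3, 2, seed = 9)
  a <- ds_weights(2)
  manual <- a[1] * (dice_loss(pyr2[[1]]$target, pyr2[[1]]$pred) +
                      ce_loss(pyr2[[1]]$target, pyr2[[1]]$pred)) +
            a[2] * (dice_loss(pyr2[[2]]$target, pyr2[[2]]$pred) +
                      ce_loss(pyr2[[2]]$target, pyr2[[2]]$pred))
  expect_equal(compound_loss(pyr2, cfg2), manual, tolerance = 1e-12)
  expect_error(compound_loss(pyr2[1], cfg2), "levels")
})

test_that("msf_loss masking semantics", {
  cfg <- loss_config(dn = 2)
  for (seed in 1:10) {
    pyr <- random_pyramid(c(6, 6, 6), 3, 2, seed = seed)
    full <- list(array(1, c(6, 6, 6)), array(1, c(3, 3, 3)))
    empty <- list(array(0, c(6, 6, 6)), array(0, c(3, 3, 3)))
    # full masks reduce to the global loss
    expect_equal(msf_loss(pyr, full, cfg), global_loss(pyr, cfg),
                 tolerance = 1e-12)
    # empty masks give exactly 0
    expect_identical(msf_loss(pyr, empty, cfg), 0)

    # equals global loss on pre-zeroed copies
    set.seed(seed + 50)
    masks <- list(random_mask(c(6, 6, 6), 0.4), random_mask(c(3, 3, 3), 0.4))
    zeroed <- lapply(1:2, function(j)
      list(target = mask_by_region(masks[[j]], pyr[[j]]$target),
           pred = mask_by_region(masks[[j]], pyr[[j]]$pred)))
    expect_equal(msf_loss(pyr, masks, cfg), global_loss(zeroed, cfg),
                 tolerance = 1e-12)

    # prediction values outside Md do not affect the loss
    pyr2 <- pyr
    out1 <- masks[[1]] == 0
    pyr2[[1]]$pred[c(out1, out1, out1)] <-
      runif(3 * sum(out1))
    expect_equal(msf_loss(pyr2, masks, cfg), msf_loss(pyr, masks, cfg),
                 tolerance = 1e-14)
  }
})

test_that("stage_loss additivity and degeneracies", {
  for (seed in 1:8) {
    pyr <- random_pyramid(c(6, 6, 6), 2, 2, seed = seed)
    masks <- list(random_mask(c(6, 6, 6), 0.3, seed + 7),
                  random_mask(c(3, 3, 3), 0.3, seed + 8))
    cfg0 <- loss_config(lambda = 0, dn = 2)
    expect_equal(stage_loss(2, pyr, masks, cfg0), stage_loss(1, pyr, cfg = cfg0),
                 tolerance = 1e-14)
    empty <- list(array(0, c(6, 6, 6)), array(0, c(3, 3, 3)))
    cfg1 <- loss_config(lambda = 1, dn = 2)
    expect_equal(stage_loss(2, pyr, empty, cfg1), stage_loss(1, pyr, cfg = cfg1))
    for (lam in c(0.5, 1, 2)) {
      cfg <- loss_config(lambda = lam, dn = 2)
      s1 <- stage_loss(1, pyr, cfg = cfg)
      s2 <- stage_loss(2, pyr, masks, cfg)
      expect_equal(s2 - s1, lam * msf_loss(pyr, masks, cfg), tolerance = 1e-12)
    }
  }
  expect_error(stage_loss(3, list()), "stage")
})

test_that("losses remain finite on clipped random input", {
  cfg <- loss_config(dn = 2)
  for (seed in 1:200) {
    set.seed(seed)
    d <- c(4, 4, 4)
    pyr <- lapply(1:2, function(j) {
      t <- array(rbinom(prod(d) * 2, 1, runif(1)), dim = c(d, 2))
      p <- array(runif(prod(d) * 2, 0, 1), dim = c(d, 2))  # includes exact 0/1
      out <- list(target = t, pred = p)
      d <<- d %/% 2L
      out
    })
    d <- c(4, 4, 4)
    masks <- list(random_mask(c(4, 4, 4), runif(1)), random_mask(c(2, 2, 2), runif(1)))
    v <- c(global_loss(pyr, cfg), msf_loss(pyr, masks, cfg),
           stage_loss(2, pyr, masks, cfg))
    expect_true(all(is.finite(v)))
  }
})
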