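test_that("one_hot separates labels and round-trips through argmax", {
  lv <- label_volume(array(c(0L, 1L, 1L, 2L), dim = c(1, 1, 4)), 3)
  oh <- one_hot(lv)
  expect_equal(oh[1, 1, , 1], c(1, 0, 0, 0))
  expect_equal(oh[1, 1, , 2], c(0, 1, 1, 0))
  expect_equal(oh[1, 1, , 3], c(0, 0, 0, 1))

  zeros <- label_volume(array(0L, dim = c(2, 3, 2)), 2)
  ohz <- one_hot(zeros)
  expect_true(all(ohz[, , , 1] == 1))
  expect_true(all(ohz[, , , 2] == 0))

  for (seed in 1:5) {
    lv <- random_label_volume(c(8, 8, 8), 4, seed)
    oh <- one_hot(lv)
    # partition: every voxel is 1 in exactly one mask
    expect_true(all(apply(oh, c(1, 2, 3), sum) == 1))
    back <- argmax_labels(oh)
    expect_identical(back$data, lv$data)
  }
})

test_that("label_volume rejects out-of-range and malformed input", {
  expect_error(label_volume(array(c(0L, 3L), dim = c(1, 1, 2)), 3), "label-range")
  expect_error(label_volume(array(-1L, dim = c(1, 1, 1)), 2), "label-range")
  expect_error(label_volume(matrix(0L, 2, 2), 2), "3D")
  expect_error(label_volume(array(0.5, dim = c(1, 1, 1)), 2), "integer")
})

test_that("misseg_region is the symmetric difference", {
  g <- array(c(1, 1, 0, 0), dim = c(1, 1, 4))
  p <- array(c(1, 0, 1, 0), dim = c(1, 1, 4))
  expect_equal(misseg_region(g, p)[1, 1, ], c(0, 1, 1, 0))

  m <- random_mask(c(5, 5, 5), seed = 3)
  expect_true(all(misseg_region(m, m) == 0))

  for (seed in 1:10) {
    a <- random_mask(c(6, 6, 6), 0.4, seed)
    b <- random_mask(c(6, 6, 6), 0.4, seed + 100)
    expect_equal(misseg_region(a, b), oracle_xor(a, b))
    # symmetry
    expect_equal(misseg_region(a, b), misseg_region(b, a))
  }
  expect_error(misseg_region(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))),
               "shape")
})

test_that("dilate_region matches a brute-force oracle and its contract", {
  center <- array(0, dim = c(5, 5, 5))
  center[3, 3, 3] <- 1
  d1 <- dilate_region(center, 1)
  # 6-connected: the centre plus its six face neighbours
  expect_equal(sum(d1), 7)
  expect_equal(d1, oracle_dilate(center, 1))
  expect_equal(dilate_region(center, 2), oracle_dilate(center, 2))
  expect_equal(dilate_region(center, 1, connectivity = 26),
               oracle_dilate(center, 1, connectivity = 26))

  empty <- array(0, dim = c(4, 4, 4))
  expect_equal(dilate_region(empty, 3), empty)

  m <- random_mask(c(6, 6, 6), 0.2, seed = 9)
  expect_identical(dilate_region(m, 0), m * 1)
  for (seed in 1:8) {
    m <- random_mask(c(6, 6, 6), 0.15, seed)
    for (f in c(1, 2)) {
      dm <- dilate_region(m, f)
      expect_equal(dm, oracle_dilate(m, f))
      expect_true(all(dm >= m))  # never removes voxels
    }
    m26 <- dilate_region(m, 1, connectivity = 26)
    expect_equal(m26, oracle_dilate(m, 1, connectivity = 26))
  }
  expect_error(dilate_region(m, -1), "non-negative")
})

test_that("merge_regions is a clamped voxel-wise OR", {
  a <- array(0, dim = c(3, 3, 3)); a[1, 1, 1] <- 1
  b <- array(0, dim = c(3, 3, 3)); b[3, 3, 3] <- 1
  expect_equal(sum(merge_regions(list(a, b))), 2)
  # idempotence: identical masks merge to themselves, not to 2
  expect_equal(merge_regions(list(a, a)), a)
  expect_true(all(merge_regions(list(a, a)) <= 1))

  for (seed in 1:6) {
    ms <- lapply(1:4, function(i) random_mask(c(6, 6, 6), 0.3, seed * 10 + i))
    expect_equal(merge_regions(ms), oracle_merge(ms))
  }
  expect_error(merge_regions(list()), "non-empty")
  expect_error(merge_regions(list(a, array(0, c(2, 2, 2)))), "shape")
})

test_that("mask_by_region zeroes outside the region, channel-wise on stacks", {
  v <- array(rnorm(27), dim = c(3, 3, 3))
  ones <- array(1, dim = c(3, 3, 3))
  zeros <- array(0, dim = c(3, 3, 3))
  expect_equal(mask_by_region(ones, v), v)
  expect_equal(mask_by_region(zeros, v), zeros)

  set.seed(4)
  stack <- array(runif(3^3 * 4), dim = c(3, 3, 3, 4))
  r <- random_mask(c(3, 3, 3), 0.5, 11)
  out <- mask_by_region(r, stack)
  for (c in 1:4) for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_identical(out[i, j, k, c], stack[i, j, k, c] * r[i, j, k])
  expect_error(mask_by_region(r, array(0, c(4, 3, 3))), "shape")
})

test_that("extract_misseg composes the pipeline and matches oracles", {
  gt <- label_volume(array(0L, c(4, 4, 4)), 3)
  # perfect prediction: all regions empty
  mr <- extract_misseg(gt, gt, factor = 2)
  expect_true(all(mr$merged == 0))
  expect_true(all(vapply(mr$per_label, sum, numeric(1)) == 0))

  # single flipped voxel appears in exactly the two affected labels
  pr <- gt; pr$data[2, 3, 2] <- 1L
  mr0 <- extract_misseg(gt, pr, factor = 0)
  expect_equal(sum(mr0$per_label[[1]]), 1)  # label 0
  expect_equal(sum(mr0$per_label[[2]]), 1)  # label 1
  expect_equal(sum(mr0$per_label[[3]]), 0)
  expect_equal(sum(mr0$merged), 1)

  for (seed in 1:10) {
    for (n in c(2, 4)) {
      g <- random_label_volume(c(8, 8, 8), n, seed)
      p <- random_label_volume(c(8, 8, 8), n, seed + 500)
      mr <- extract_misseg(g, p, factor = 0)
      # factor 0: merged count equals the number of differing voxels
      expect_equal(sum(mr$merged), sum(g$data != p$data))
      mr2 <- extract_misseg(g, p, factor = 2)
      for (i in seq_len(n)) {
        mn <- oracle_xor(one_hot(g)[, , , i], one_hot(p)[, , , i])
        expect_equal(mr2$per_label[[i]], mn)
        expect_equal(mr2$per_label_dilated[[i]], oracle_dilate(mn, 2))
        # Mn subset of Mdn subset of Md
        expect_true(all(mr2$per_label[[i]] <= mr2$per_label_dilated[[i]]))
        expect_true(all(mr2$per_label_dilated[[i]] <= mr2$merged))
      }
      expect_equal(mr2$merged, oracle_merge(mr2$per_label_dilated))
    }
  }
})

test_that("extract_misseg can exclude background", {
  gt <- label_volume(array(0L, c(4, 4, 4)), 3)
  pr <- gt; pr$data[1, 1, 1] <- 2L
  mr <- extract_misseg(gt, pr, factor = 0, include_background = FALSE)
  expect_equal(sum(mr$per_label[[1]]), 0)   # background excluded
  expect_equal(sum(mr$per_label[[3]]), 1)
  expect_equal(sum(mr$merged), 1)
})
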