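test_that("phantom generation is deterministic and satisfies label invariants", {
  spec <- phantom_spec(seed = 42)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$labels$data, p2$labels$data)

  expect_s3_class(p1$labels, "label_volume")
  expect_true(all(p1$labels$data >= 0 & p1$labels$data < 4))
  # all four classes present, nested shells roughly sized as ellipsoid bands
  counts <- tabulate(as.vector(p1$labels$data) + 1L, 4)
  expect_true(all(counts > 0))
  expect_gt(counts[1], prod(spec$shape) * 0.25)   # background majority
})

test_that("bias field and noise options perturb the image, not the labels", {
  base <- generate_phantom(phantom_spec(seed = 21))
  biased <- generate_phantom(phantom_spec(seed = 21, bias_field = TRUE,
                                          noise_std = 0.05))
  expect_identical(base$labels$data, biased$labels$data)
  expect_false(identical(base$image, biased$image))
  expect_true(all(is.finite(biased$image)))
})

test_that("a noiseless well-separated phantom is recovered by thresholding", {
  spec <- phantom_spec(boundary_jitter = 0, noise_std = 0,
                       intensity_means = c(0, 1, 2, 3),
                       intensity_stds = rep(1e-6, 4), seed = 9)
  p <- generate_phantom(spec)
  # nearest-mean classification must recover the labels exactly
  recovered <- round(p$image)
  expect_identical(array(as.integer(recovered), dim = spec$shape),
                   p$labels$data)
})

test_that("overlapping intensities make the Bayes classifier imperfect", {
  spec <- phantom_spec(seed = 5)   # defaults: adjacent means ~1 sd apart
  p <- generate_phantom(spec)
  mu <- spec$intensity_means
  # per-voxel nearest-mean decision (equal sds -> Bayes rule)
  dist <- sapply(mu, function(m) (as.vector(p$image) - m)^2)
  bayes <- max.col(-dist, ties.method = "first") - 1L
  acc <- mean(bayes == as.vector(p$labels$data))
  expect_lt(acc, 1)
  expect_gt(acc, 0.5)
})

test_that("noise monotonically degrades the fixed-threshold oracle", {
  accs <- sapply(c(0, 0.1, 0.25), function(ns) {
    med <- sapply(1:5, function(sd0) {
      spec <- phantom_spec(noise_std = ns, seed = sd0)
      p <- generate_phantom(spec)
      mu <- spec$intensity_means
      dist <- sapply(mu, function(m) (as.vector(p$image) - m)^2)
      bayes <- max.col(-dist, ties.method = "first") - 1L
      mean(bayes == as.vector(p$labels$data))
    })
    median(med)
  })
  expect_true(all(diff(accs) < 0))
})

test_that("small inserts occupy under 2% of voxels", {
  spec <- phantom_spec(n_inserts = 1, seed = 3)
  p <- generate_phantom(spec)
  expect_equal(p$labels$n_labels, 5L)
  ins <- sum(p$labels$data == 4L)
  expect_gt(ins, 0)
  expect_lt(ins / prod(spec$shape), 0.02)
})

test_that("collapsed shell geometry is rejected", {
  spec <- phantom_spec(shape = c(8, 8, 8), n_labels = 10)
  expect_error(generate_phantom(spec), "geometry|collapsed")
})

test_that("generate_dataset writes a 4:1 split manifest and reproduces bitwise", {
  dir1 <- file.path(tempdir(), "ph1")
  dir2 <- file.path(tempdir(), "ph2")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE))
  spec <- phantom_spec(shape = c(16, 16, 16), seed = 77)
  mf <- generate_dataset(spec, 10, dir1)
  expect_equal(sum(mf$subjects$split == "train"), 8)
  expect_equal(sum(mf$subjects$split == "test"), 2)
  expect_equal(nrow(mf$subjects), 10)

  mf2 <- generate_dataset(spec, 10, dir2)
  for (f in list.files(dir1)) {
    if (grepl("manifest", f)) next
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }

  # empty dataset: empty manifest, no volume files
  dir3 <- file.path(tempdir(), "ph3")
  on.exit(unlink(dir3, recursive = TRUE), add = TRUE)
  mf0 <- generate_dataset(spec, 0, dir3)
  expect_equal(nrow(mf0$subjects), 0)
  expect_length(list.files(dir3, pattern = "nii"), 0)
})

test_that("load_dataset round-trips images and labels", {
  dir <- file.path(tempdir(), "ph-rt")
  on.exit(unlink(dir, recursive = TRUE))
  spec <- phantom_spec(shape = c(16, 16, 16), seed = 13)
  generate_dataset(spec, 3, dir)
  subs <- load_dataset(dir, "all")
  expect_length(subs, 3)
  s <- spec; s$seed <- msfseg:::subject_seeds(77, 1)  # wrong seed: different
  ref <- generate_phantom({ sp <- spec; sp$seed <- msfseg:::subject_seeds(13, 3)[1]; sp })
  expect_equal(subs[[1]]$image, ref$image, tolerance = 1e-6)  # float32 storage
  expect_identical(subs[[1]]$labels$data, ref$labels$data)
})
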