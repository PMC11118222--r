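#' Phantom specification
#'
#' Describes a synthetic multi-label 3D phantom: nested ellipsoidal tissue
#' shells (background, CSF-like outer shell, GM-like shell, WM-like core)
#' with optional small ellipsoidal inserts (hippocampus-like structures)
#' inside the core. The geometry mimics what boundary-focused segmentation
#' losses target: adjacent/nested classes, ambiguous jittered boundaries,
#' small structures, and per-class intensity distributions that overlap.
#'
#' @param shape length-3 grid size (default 24^3, divisible by 2^3 for the
#'   desk network preset).
#' @param n_labels number of shell classes including background (default 4).
#' @param n_inserts number of small insert labels added inside the core
#'   (default 0; each insert is its own label, so N becomes
#'   \code{n_labels + n_inserts}).
#' @param intensity_means per-label mean intensities (length
#'   \code{n_labels + n_inserts}). Defaults place adjacent classes about one
#'   standard deviation apart, so boundary voxels are genuinely ambiguous.
#' @param intensity_stds per-label intensity standard deviations.
#' @param boundary_jitter amplitude (voxels) of the smooth radial
#'   perturbation applied to shell boundaries.
#' @param noise_std additive Gaussian noise on top of the per-label draw.
#' @param bias_field multiply the image by a smooth low-frequency field.
#' @param spacing voxel size (mm).
#' @param seed integer seed making the phantom fully reproducible.
#' @return list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(24L, 24L, 24L), n_labels = 4L,
                         n_inserts = 0L,
                         intensity_means = NULL, intensity_stds = NULL,
                         boundary_jitter = 1.5, noise_std = 0,
                         bias_field = FALSE, spacing = c(1, 1, 1),
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_labels >= 2L,
            n_inserts >= 0L, boundary_jitter >= 0, noise_std >= 0)
  ntot <- n_labels + n_inserts
  if (is.null(intensity_means)) {
    base <- c(0, 0.3, 0.55, 0.8)
    intensity_means <- if (ntot <= 4L) base[seq_len(ntot)]
      else c(base, seq(0.95, by = 0.15, length.out = ntot - 4L))
  }
  if (is.null(intensity_stds)) intensity_stds <- rep(0.12, ntot)
  if (length(intensity_means) != ntot || length(intensity_stds) != ntot)
    stop("need one intensity mean and std per label (", ntot, ")")
  structure(list(shape = shape, n_labels = as.integer(n_labels),
                 n_inserts = as.integer(n_inserts),
                 intensity_means = intensity_means,
                 intensity_stds = intensity_stds,
                 boundary_jitter = boundary_jitter, noise_std = noise_std,
                 bias_field = isTRUE(bias_field),
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth random field in [-1,1]-ish: coarse white noise trilinearly upsampled
smooth_field <- function(shape, coarse = 6L) {
  g <- array(rnorm(coarse^3), dim = rep(coarse, 3L))
  ax <- lapply(shape, function(n) {
    # continuous coordinate of each fine voxel in coarse-grid units
    (seq_len(n) - 0.5) / n * (coarse - 1) + 0.5
  })
  i0 <- lapply(ax, function(a) pmin(pmax(floor(a), 1), coarse - 1))
  w <- Map(function(a, i) a - i, ax, i0)
  out <- array(0, dim = shape)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - w[[1]] else w[[1]]
    wy <- if (dy == 0) 1 - w[[2]] else w[[2]]
    wz <- if (dz == 0) 1 - w[[3]] else w[[3]]
    sub <- g[cbind(rep(i0[[1]] + dx, times = shape[2] * shape[3]),
                   rep(rep(i0[[2]] + dy, each = shape[1]), times = shape[3]),
                   rep(i0[[3]] + dz, each = shape[1] * shape[2]))]
    wt <- as.vector(outer(outer(wx, wy), wz))
    out <- out + array(sub * wt, dim = shape)
  }
  out / stats::sd(out)
}

#' Generate one synthetic phantom
#'
#' Builds the label map from nested ellipsoidal shells whose radial
#' boundaries are perturbed by a smooth random field (amplitude
#' \code{boundary_jitter} voxels), optionally places small ellipsoidal
#' inserts inside the core, then draws each voxel's intensity from its
#' label's Gaussian, adds optional bias field and noise. Ground-truth labels
#' stay clean; all ambiguity lives in the image. Fully reproducible from
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{image} (3D numeric array) and \code{labels}
#'   (a \code{\link{label_volume}}).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  d <- spec$shape
  ctr <- (d + 1) / 2
  semi <- d / 2 - 1.5          # outer semi-axes leave a background rim
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  # normalized elliptic radius in "outer-boundary voxels" units
  r <- sqrt(((co$x - ctr[1]) / semi[1])^2 + ((co$y - ctr[2]) / semi[2])^2 +
              ((co$z - ctr[3]) / semi[3])^2) * min(semi)
  r <- array(r, dim = d)
  # shell thresholds: equally spaced radii from core to outer boundary
  n_sh <- spec$n_labels - 1L                 # non-background shells
  thr <- min(semi) * seq_len(n_sh) / n_sh    # innermost label has smallest radius
  # each shell must be at least one voxel thick, or inner and outer radii
  # coincide on the grid
  if (min(semi) / n_sh < 1)
    stop("shell geometry collapsed (inner radius >= outer on this grid)")
  jit <- if (spec$boundary_jitter > 0)
    spec$boundary_jitter * smooth_field(d) else array(0, dim = d)
  rj <- r + jit
  lab <- array(0L, dim = d)
  # label n_labels-1 is the core (smallest radius), label 1 the outer shell;
  # assign outermost first so inner shells overwrite
  for (k in rev(seq_len(n_sh))) {
    lab[rj <= thr[k]] <- spec$n_labels - k
  }
  # inserts: small ellipsoids placed inside the core region
  if (spec$n_inserts > 0L) {
    core_r <- thr[1]
    for (ii in seq_len(spec$n_inserts)) {
      ang <- runif(2, 0, 2 * pi)
      rad <- runif(1, 0, 0.4 * core_r)
      cen <- ctr + rad * c(cos(ang[1]) * sin(ang[2]), sin(ang[1]) * sin(ang[2]),
                           cos(ang[2]))
      ax <- runif(3, 0.08, 0.14) * min(d)
      ri <- ((co$x - cen[1]) / ax[1])^2 + ((co$y - cen[2]) / ax[2])^2 +
        ((co$z - cen[3]) / ax[3])^2
      lab[array(ri, dim = d) <= 1] <- spec$n_labels - 1L + ii
    }
  }
  ntot <- spec$n_labels + spec$n_inserts
  mu <- spec$intensity_means[lab + 1L]
  sdv <- spec$intensity_stds[lab + 1L]
  img <- array(mu + sdv * rnorm(length(lab)), dim = d)
  if (spec$bias_field) img <- img * (1 + 0.2 * smooth_field(d, coarse = 3L))
  if (spec$noise_std > 0) img <- img + rnorm(length(img), sd = spec$noise_std)
  list(image = img,
       labels = label_volume(lab, n_labels = ntot, spacing = spec$spacing))
}

#' Generate a phantom dataset on disk
#'
#' Writes \code{n_subjects} image/label NIfTI pairs
#' (\code{sub-XXX_img.nii.gz}, \code{sub-XXX_seg.nii.gz}) plus a JSON
#' manifest recording each subject's seed, a hash of the spec, and a 4:1
#' train:test split. Regenerating from the manifest seeds reproduces the
#' files bit-for-bit.
#'
#' @param spec a \code{\link{phantom_spec}}; per-subject seeds are derived
#'   deterministically from \code{spec$seed}.
#' @param n_subjects number of phantoms.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (a list with \code{subjects} data.frame
#'   and \code{spec_hash}).
#' @export
generate_dataset <- function(spec, n_subjects, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 0)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable")
  seeds <- subject_seeds(spec$seed, n_subjects)
  split <- rep("train", n_subjects)
  if (n_subjects > 0) {
    n_test <- max(0L, round(n_subjects / 5))   # 4:1 train:test
    if (n_test > 0) split[seq(n_subjects - n_test + 1L, n_subjects)] <- "test"
  }
  subjects <- data.frame(id = sprintf("sub-%03d", seq_len(n_subjects)),
                         seed = seeds, split = split,
                         stringsAsFactors = FALSE)
  if (n_subjects == 0) subjects <- subjects[0, ]
  for (i in seq_len(n_subjects)) {
    s <- spec; s$seed <- seeds[i]
    ph <- generate_phantom(s)
    write_volume(ph$image, file.path(out_dir, paste0(subjects$id[i], "_img.nii.gz")),
                 spacing = spec$spacing)
    write_volume(ph$labels, file.path(out_dir, paste0(subjects$id[i], "_seg.nii.gz")))
  }
  manifest <- list(spec_hash = spec_hash(spec), n_subjects = n_subjects,
                   spec = unclass(spec), subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

subject_seeds <- function(seed, n) {
  if (n == 0) return(integer(0))
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}

spec_hash <- function(spec) {
  s <- unclass(spec)
  paste0("sha-", substr(digest_chr(paste(names(s), sapply(s, paste, collapse = ","),
                                         collapse = ";")), 1, 12))
}

# tiny stable string hash (hex of a rolling checksum); enough to detect
# spec drift in manifests without external dependencies
digest_chr <- function(s) {
  v <- utf8ToInt(s)
  h1 <- 5381; h2 <- 52711
  for (ch in v) {
    h1 <- (h1 * 33 + ch) %% 2147483647
    h2 <- (h2 * 131 + ch) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Load a phantom dataset written by generate_dataset
#'
#' @param dir directory containing the NIfTI pairs and manifest.json.
#' @param split "train", "test" or "all".
#' @return list of subjects, each a list with \code{id}, \code{image},
#'   \code{labels}.
#' @export
load_dataset <- function(dir, split = "all") {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  subj <- mf$subjects
  if (split != "all") subj <- subj[subj$split == split, , drop = FALSE]
  lapply(seq_len(nrow(subj)), function(i) {
    img <- read_volume(file.path(dir, paste0(subj$id[i], "_img.nii.gz")))
    seg <- read_volume(file.path(dir, paste0(subj$id[i], "_seg.nii.gz")))
    list(id = subj$id[i], image = img$data,
         labels = label_volume(seg$data, spacing = seg$spacing))
  })
}
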