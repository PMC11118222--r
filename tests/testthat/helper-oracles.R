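# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain voxel loops, sharing no code with the package.

oracle_xor <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out[i, j, k] <- as.numeric(a[i, j, k] != b[i, j, k])
  out
}

# one elementary binary dilation with an explicit structuring element offset
# list; repeated `factor` times
oracle_dilate <- function(mask, factor, connectivity = 6) {
  offs <- if (connectivity == 6) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
         c(0, 0, -1), c(0, 0, 0))
  } else {
    o <- list()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
      o[[length(o) + 1]] <- c(dx, dy, dz)
    o
  }
  d <- dim(mask)
  cur <- mask
  for (it in seq_len(factor)) {
    nxt <- array(0, dim = d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      v <- 0
      for (of in offs) {
        ii <- i - of[1]; jj <- j - of[2]; kk <- k - of[3]
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            kk >= 1 && kk <= d[3] && cur[ii, jj, kk] == 1) { v <- 1; break }
      }
      nxt[i, j, k] <- v
    }
    cur <- nxt
  }
  cur
}

oracle_merge <- function(masks) {
  d <- dim(masks[[1]])
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    any1 <- 0
    for (m in masks) if (m[i, j, k] == 1) any1 <- 1
    out[i, j, k] <- any1
  }
  out
}

oracle_dice_loss <- function(target, pred, eps = 1e-7) {
  num <- 0; st <- 0; sp <- 0
  tv <- as.vector(target); pv <- as.vector(pred)
  for (i in seq_along(tv)) {
    num <- num + tv[i] * pv[i]
    st <- st + tv[i]; sp <- sp + pv[i]
  }
  if (st == 0 && sp == 0) return(0)
  -2 * num / (st + sp + eps)
}

oracle_ce_loss <- function(target, pred, eps = 1e-7) {
  tv <- as.vector(target); pv <- pmin(pmax(as.vector(pred), eps), 1 - eps)
  s <- 0
  for (i in seq_along(tv))
    s <- s + tv[i] * log(pv[i]) + (1 - tv[i]) * log(1 - pv[i])
  -s / length(tv)
}

# boundary voxels by explicit 6-neighbour scan
oracle_boundary <- function(mask) {
  d <- dim(mask)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 1) next
    nb <- FALSE
    for (of in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      ii <- i + of[1]; jj <- j + of[2]; kk <- k + of[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          mask[ii, jj, kk] == 0) { nb <- TRUE; break }
    }
    if (nb) pts <- rbind(pts, c(i, j, k))
  }
  pts
}

# all-pairs directed 95th percentile Hausdorff (max-of-directed convention)
oracle_hd95 <- function(a, b, spacing = c(1, 1, 1), percentile = 95) {
  pa <- oracle_boundary(a); pb <- oracle_boundary(b)
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  pa <- sweep(pa, 2, spacing, `*`); pb <- sweep(pb, 2, spacing, `*`)
  dmat <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
    dmat[i, j] <- sqrt(sum((pa[i, ] - pb[j, ])^2))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  max(unname(quantile(dab, percentile / 100, type = 7)),
      unname(quantile(dba, percentile / 100, type = 7)))
}

random_label_volume <- function(dims, n_labels, seed) {
  set.seed(seed)
  label_volume(array(sample(0:(n_labels - 1), prod(dims), replace = TRUE),
                     dim = dims), n_labels)
}

random_mask <- function(dims, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(as.numeric(runif(prod(dims)) < p), dim = dims)
}

# random supervision pyramid with dn levels starting at `dims`
random_pyramid <- function(dims, n_ch, dn, seed) {
  set.seed(seed)
  out <- vector("list", dn)
  d <- dims
  for (j in seq_len(dn)) {
    out[[j]] <- list(target = array(as.numeric(runif(prod(d) * n_ch) < 0.5),
                                    dim = c(d, n_ch)),
                     pred = array(runif(prod(d) * n_ch, 0.01, 0.99),
                                  dim = c(d, n_ch)))
    d <- d %/% 2L
  }
  out
}

small_training_set <- function(n = 3, seed = 100, shape = c(16L, 16L, 16L)) {
  lapply(seq_len(n), function(i)
    generate_phantom(phantom_spec(shape = shape, seed = seed + i))[
      c("image", "labels")])
}

# step-through oracle of the plateau rule: walk the EMA history epoch by
# epoch, tracking the best value before the trailing window and the cool-down
oracle_lr_walk <- function(ema, lr0, pat = 30, imp = 5e-3, fac = 5) {
  lr <- lr0
  decays <- integer(0)
  last <- 0
  for (n in seq_along(ema)) {
    if (n <= pat || n - last <= pat) next
    window <- ema[(n - pat + 1):n]
    before <- ema[1:(n - pat)]
    if (min(window) > min(before) - imp) {
      lr <- lr / fac
      decays <- c(decays, n)
      last <- n
    }
  }
  list(lr = lr, decays = decays)
}

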