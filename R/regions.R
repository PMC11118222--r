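#' Per-label mis-segmentation region
#'
#' The mis-segmentation region of one label is the set of voxels where the
#' ground-truth mask and the predicted mask disagree: the symmetric
#' difference \eqn{(y_n \cup y'_n) - (y_n \cap y'_n)}.
#'
#' @param gt_mask binary 3D array (ground-truth mask for one label).
#' @param pred_mask binary 3D array of the same shape (predicted mask).
#' @return Binary 3D array, 1 where exactly one of the inputs is 1.
#' @examples
#' g <- array(c(1, 1, 0, 0), dim = c(1, 1, 4))
#' p <- array(c(1, 0, 1, 0), dim = c(1, 1, 4))
#' misseg_region(g, p)[1, 1, ]
#' @export
misseg_region <- function(gt_mask, pred_mask) {
  if (!identical(dim(gt_mask), dim(pred_mask)))
    stop("gt_mask and pred_mask must have identical shapes")
  if (!is_binary_grid(as.array(gt_mask)) || !is_binary_grid(as.array(pred_mask)))
    stop("masks must be binary 3D grids")
  out <- array(as.numeric(xor(gt_mask == 1, pred_mask == 1)), dim = dim(gt_mask))
  out
}

# shift a 3D array by one voxel along `axis` in direction `dir`, zero-filling
shift1 <- function(m, axis, dir) {
  d <- dim(m)
  out <- array(0, dim = d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (dir > 0) {
    idx_dst[[axis]] <- seq_len(d[axis])[-1L]
    idx_src[[axis]] <- seq_len(d[axis] - 1L)
  } else {
    idx_dst[[axis]] <- seq_len(d[axis] - 1L)
    idx_src[[axis]] <- seq_len(d[axis])[-1L]
  }
  if (d[axis] > 1L)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Morphological dilation of a binary region
#'
#' Applies binary dilation \code{factor} times with an elementary 3D
#' structuring element. The default element is the 6-connected cross
#' (face-adjacent neighbours), so \code{factor} acts as an interpretable
#' city-block radius; a 26-connected cube element is available via
#' \code{connectivity = 26}. \code{factor = 0} returns the input unchanged.
#' Dilation never removes voxels.
#'
#' @param mask binary 3D array.
#' @param factor non-negative integer, number of elementary dilations.
#' @param connectivity 6 (face-adjacent cross, default) or 26 (full cube).
#' @return Binary 3D array containing the input.
#' @export
dilate_region <- function(mask, factor, connectivity = 6) {
  if (length(factor) != 1L || is.na(factor) || factor < 0 || factor != round(factor))
    stop("dilation factor must be a non-negative integer")
  if (!is_binary_grid(as.array(mask))) stop("mask must be a binary 3D grid")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  out <- array(as.numeric(mask), dim = dim(mask))
  if (factor == 0) return(out)
  for (it in seq_len(factor)) {
    acc <- out
    if (connectivity == 6) {
      for (ax in 1:3) for (dr in c(-1L, 1L))
        acc <- pmax(acc, shift1(out, ax, dr))
    } else {
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        s <- out
        if (dx != 0) s <- shift1(s, 1L, dx)
        if (dy != 0) s <- shift1(s, 2L, dy)
        if (dz != 0) s <- shift1(s, 3L, dz)
        acc <- pmax(acc, s)
      }
    }
    out <- acc
  }
  out
}

#' Merge per-label dilated regions into a global error mask
#'
#' Superimposes the N per-label (dilated) mis-segmentation masks. The
#' superposition is clamped to a binary mask (voxel-wise logical OR), since
#' the merged region is used multiplicatively to mask volumes, where counts
#' greater than one would be meaningless.
#'
#' @param dilated list of N binary 3D arrays, all of the same shape.
#' @return Binary 3D array: 1 where any input mask is 1.
#' @export
merge_regions <- function(dilated) {
  if (!is.list(dilated) || length(dilated) == 0L)
    stop("dilated must be a non-empty list of masks")
  d <- dim(dilated[[1L]])
  out <- array(0, dim = d)
  for (m in dilated) {
    if (!identical(dim(m), d)) stop("all masks must share one shape")
    out <- pmax(out, as.numeric(m))
  }
  array(as.numeric(out > 0), dim = d)
}

#' Mask a volume (or channel stack) by a binary region
#'
#' Element-wise product of a binary region with a volume; voxels outside the
#' region become exactly zero. A 4D channel stack is masked channel-wise.
#'
#' @param region binary 3D array.
#' @param volume 3D array of the same spatial shape, or a 4D
#'   \code{(X, Y, Z, C)} stack.
#' @return Same shape as \code{volume}.
#' @export
mask_by_region <- function(region, volume) {
  dr <- dim(region)
  dv <- dim(volume)
  if (length(dv) == 3L) {
    if (!identical(dr, dv)) stop("region and volume spatial shapes differ")
    return(volume * region)
  }
  if (length(dv) == 4L) {
    if (!identical(dr, dv[1:3])) stop("region and stack spatial shapes differ")
    return(volume * as.vector(region))  # recycles region across channels
  }
  stop("volume must be a 3D array or 4D channel stack")
}

#' Extract mis-segmentation regions between two label volumes
#'
#' The full region-extraction pipeline: one-hot both volumes, take the
#' per-label symmetric difference \eqn{M_n}, dilate each by \code{factor}
#' to \eqn{Md_n}, and merge across labels into the global binary error mask
#' \eqn{Md}. Background (label 0) participates like any other label by
#' default; set \code{include_background = FALSE} to exclude it.
#'
#' @param gt,pred \code{\link{label_volume}}s with matching shape and
#'   \code{n_labels} (plain integer arrays are accepted).
#' @param factor non-negative integer dilation factor (default 2).
#' @param connectivity structuring element, see \code{\link{dilate_region}}.
#' @param include_background include label 0 in the merge (default TRUE).
#' @return Object of class \code{misseg_regions}: list with \code{per_label}
#'   (list of N binary arrays \eqn{M_n}), \code{per_label_dilated}
#'   (\eqn{Md_n}), \code{merged} (\eqn{Md}), and \code{dilation_factor}.
#' @examples
#' gt <- label_volume(array(0L, c(3, 3, 3)), 2)
#' pr <- gt; pr$data[2, 2, 2] <- 1L
#' r <- extract_misseg(gt, pr, factor = 0)
#' sum(r$merged)
#' @export
extract_misseg <- function(gt, pred, factor = 2, connectivity = 6,
                           include_background = TRUE) {
  gt <- as_label_volume(gt)
  pred <- as_label_volume(pred, n_labels = gt$n_labels)
  if (!identical(dim(gt$data), dim(pred$data)))
    stop("gt and pred must share shape")
  if (gt$n_labels != pred$n_labels) stop("gt and pred must share n_labels")
  n <- gt$n_labels
  oh_g <- one_hot(gt)
  oh_p <- one_hot(pred)
  labs <- if (include_background) seq_len(n) else seq_len(n)[-1L]
  per <- vector("list", n)
  per_d <- vector("list", n)
  d <- dim(gt$data)
  for (i in seq_len(n)) {
    if (i %in% labs) {
      m <- misseg_region(array(oh_g[, , , i], d), array(oh_p[, , , i], d))
      per[[i]] <- m
      per_d[[i]] <- dilate_region(m, factor, connectivity)
    } else {
      per[[i]] <- per_d[[i]] <- array(0, dim = d)
    }
  }
  merged <- merge_regions(per_d)
  structure(list(per_label = per, per_label_dilated = per_d, merged = merged,
                 dilation_factor = as.integer(factor)),
            class = "misseg_regions")
}

#' @export
print.misseg_regions <- function(x, ...) {
  cnt <- vapply(x$per_label, sum, numeric(1))
  cat(sprintf("<misseg_regions> %d labels, dilation factor %d\n",
              length(x$per_label), x$dilation_factor))
  cat("  per-label error voxels:", paste(cnt, collapse = ", "), "\n")
  cat("  merged (dilated) error voxels:", sum(x$merged), "of",
      length(x$merged), "\n")
  invisible(x)
}
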