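#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} for two binary masks; 1 is perfect
#' overlap, 0 no overlap. Defined as 1 when both masks are empty.
#'
#' @param a,b binary 3D arrays of the same shape.
#' @return scalar in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share shape")
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

# boundary voxels: mask voxels with at least one face-adjacent non-mask
# neighbour (volume faces count as outside)
boundary_voxels <- function(mask) {
  m <- array(as.numeric(mask), dim = dim(mask))
  interior <- m
  for (ax in 1:3) for (dr in c(-1L, 1L))
    interior <- interior * shift1(m, ax, dr)
  b <- m * (1 - interior)
  which(b == 1, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance
#'
#' Boundary-to-boundary robust surface distance: extract the boundary voxels
#' of each mask, compute the two directed distance sets (each boundary point
#' of one mask to its nearest boundary point of the other), take the 95th
#' percentile of each direction (linear interpolation between order
#' statistics), and return the maximum of the two. Distances are Euclidean in
#' physical units (voxel coordinates scaled by \code{spacing}).
#'
#' @param a,b binary 3D arrays of the same shape.
#' @param spacing per-axis voxel size (mm); scalar or length 3.
#' @param percentile percentile of the directed distance distributions
#'   (default 95).
#' @param pooled if TRUE, pool both directed distance sets and take a single
#'   percentile instead of the max-of-directed convention.
#' @return non-negative scalar, or \code{NA_real_} when either mask is empty
#'   (reported as undefined rather than raising mid-evaluation).
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1), percentile = 95, pooled = FALSE) {
  if (!identical(dim(a), dim(b))) stop("masks must share shape")
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  pa <- boundary_voxels(a)
  pb <- boundary_voxels(b)
  pa <- sweep(matrix(as.numeric(pa), ncol = 3L), 2L, spacing, `*`)
  pb <- sweep(matrix(as.numeric(pb), ncol = 3L), 2L, spacing, `*`)
  dab <- min_dists(pa, pb)
  dba <- min_dists(pb, pa)
  q <- percentile / 100
  if (pooled) {
    unname(stats::quantile(c(dab, dba), q, type = 7))
  } else {
    max(unname(stats::quantile(dab, q, type = 7)),
        unname(stats::quantile(dba, q, type = 7)))
  }
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Per-label Dice and HD95 from the one-hot masks, their means, and the total
#' mis-segmentation voxel count (symmetric-difference union, no dilation).
#'
#' @param gt,pred \code{\link{label_volume}}s with matching shape and
#'   \code{n_labels}.
#' @param spacing voxel size for HD95; defaults to the ground truth's.
#' @param include_background_in_mean include label 0 when averaging
#'   (default TRUE; the per-label table always includes it).
#' @return object of class \code{eval_report}: list with \code{per_label}
#'   (data.frame label/dice/hd95), \code{mean_dice}, \code{mean_hd95}
#'   (NA-aware), and \code{misseg_voxels}.
#' @export
evaluate <- function(gt, pred, spacing = NULL,
                     include_background_in_mean = TRUE) {
  gt <- as_label_volume(gt)
  pred <- as_label_volume(pred, n_labels = gt$n_labels)
  if (gt$n_labels != pred$n_labels) stop("n_labels mismatch")
  if (!identical(dim(gt$data), dim(pred$data))) stop("shape mismatch")
  if (is.null(spacing)) spacing <- gt$spacing
  n <- gt$n_labels
  oh_g <- one_hot(gt)
  oh_p <- one_hot(pred)
  d <- dim(gt$data)
  dice <- hd <- numeric(n)
  for (i in seq_len(n)) {
    ag <- array(oh_g[, , , i], d)
    ap <- array(oh_p[, , , i], d)
    dice[i] <- dice_coefficient(ag, ap)
    hd[i] <- hd95(ag, ap, spacing)
  }
  keep <- if (include_background_in_mean) seq_len(n) else seq_len(n)[-1L]
  mr <- extract_misseg(gt, pred, factor = 0)
  structure(list(
    per_label = data.frame(label = 0:(n - 1L), dice = dice, hd95 = hd),
    mean_dice = mean(dice[keep]),
    mean_hd95 = if (all(is.na(hd[keep]))) NA_real_ else mean(hd[keep], na.rm = TRUE),
    misseg_voxels = sum(mr$merged)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$per_label, row.names = FALSE)
  cat(sprintf("  mean Dice %.4f | mean HD95 %s | mis-seg voxels %d\n",
              x$mean_dice,
              if (is.na(x$mean_hd95)) "undefined" else sprintf("%.4f", x$mean_hd95),
              x$misseg_voxels))
  invisible(x)
}
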