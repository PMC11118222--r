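#' Construct a label volume
#'
#' A label volume is a 3D integer grid assigning one of \code{n_labels}
#' classes (0-based indices \code{0..n_labels-1}) to each voxel, plus the
#' voxel spacing in mm. It represents both ground-truth segmentations and
#' argmax-decoded network predictions.
#'
#' @param data 3D array (or object coercible to one) of integer class indices.
#' @param n_labels number of classes N. Defaults to \code{max(data) + 1}.
#' @param spacing numeric length-3 voxel size per axis in mm (default isotropic 1).
#' @return An object of class \code{label_volume}: a list with elements
#'   \code{data} (3D integer array), \code{n_labels} and \code{spacing}.
#' @examples
#' lv <- label_volume(array(0:1, dim = c(2, 2, 2)), n_labels = 2)
#' lv$n_labels
#' @export
label_volume <- function(data, n_labels = NULL, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("label volume data must be a 3D array, got ", length(dim(data)), " dims")
  if (any(dim(data) < 1L)) stop("all three axis lengths must be >= 1")
  if (anyNA(data)) stop("label volume contains NA")
  if (any(data != round(data))) stop("label volume values must be integers")
  storage.mode(data) <- "integer"
  if (is.null(n_labels)) n_labels <- max(data) + 1L
  n_labels <- as.integer(n_labels)
  if (n_labels < 1L) stop("n_labels must be positive")
  if (any(data < 0L) || any(data >= n_labels))
    stop("label values must lie in [0, ", n_labels - 1L, "] (label-range error)")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  structure(list(data = data, n_labels = n_labels, spacing = spacing),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %dx%dx%d voxels, %d labels, spacing %s mm\n",
              d[1], d[2], d[3], x$n_labels,
              paste(format(x$spacing), collapse = " x ")))
  tab <- tabulate(as.vector(x$data) + 1L, nbins = x$n_labels)
  cat("  voxels per label:", paste(tab, collapse = ", "), "\n")
  invisible(x)
}

is_binary_grid <- function(m) {
  is.array(m) && length(dim(m)) == 3L && all(m == 0 | m == 1)
}

as_label_volume <- function(x, n_labels = NULL, spacing = c(1, 1, 1)) {
  if (inherits(x, "label_volume")) x else label_volume(x, n_labels, spacing)
}

#' One-hot encode a label volume
#'
#' Separates an N-class label volume into N binary masks, one per label:
#' mask \code{n} (1-based slot \code{n + 1}) is 1 exactly where the volume
#' equals label \code{n}. The masks partition the grid: every voxel is 1 in
#' exactly one mask.
#'
#' @param label_volume a \code{\link{label_volume}} (or 3D integer array).
#' @param n_labels number of classes; taken from the volume when omitted.
#' @return 4D numeric array of shape \code{c(dim, n_labels)} with binary values.
#' @examples
#' lv <- label_volume(array(c(0L, 1L, 1L, 2L), dim = c(1, 1, 4)), 3)
#' oh <- one_hot(lv)
#' dim(oh)
#' @export
one_hot <- function(label_volume, n_labels = NULL) {
  lv <- as_label_volume(label_volume, n_labels)
  d <- dim(lv$data)
  n <- lv$n_labels
  out <- array(0, dim = c(d, n))
  v <- as.vector(lv$data)
  # linear index into the 4D array: voxel + (label)*prod(d)
  out[seq_along(v) + v * prod(d)] <- 1
  out
}

#' Per-voxel argmax decode of a channel stack
#'
#' Collapses an N-channel score stack to a label volume by taking, at every
#' voxel, the channel with the highest score. Exact ties are broken toward
#' the lowest label index, so the decode is deterministic.
#'
#' @param prob_stack 4D array \code{(X, Y, Z, N)} of per-class scores.
#' @param spacing voxel spacing passed through to the result.
#' @return A \code{\link{label_volume}} with values in \code{0..N-1}.
#' @export
argmax_labels <- function(prob_stack, spacing = c(1, 1, 1)) {
  d <- dim(prob_stack)
  if (length(d) != 4L) stop("prob_stack must be a 4D (X,Y,Z,N) array")
  m <- matrix(prob_stack, nrow = prod(d[1:3]), ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  label_volume(array(lab, dim = d[1:3]), n_labels = d[4], spacing = spacing)
}
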