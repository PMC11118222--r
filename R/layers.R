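# Internal layer primitives. A feature map is a list(x = S x C matrix,
# dims = c(X, Y, Z)) with voxels in column-major (x fastest) order. Every
# forward returns list(out, cache); every backward consumes (cache, gout) and
# returns the input gradient plus parameter gradients.

fm <- function(x, dims) list(x = x, dims = as.integer(dims))

conv_out_dims <- function(dims, stride) {
  if (stride == 1L) dims else as.integer((dims - 1L) %/% stride + 1L)
}

conv3_fw <- function(f, W, b, stride = 1L) {
  out <- conv3_gemm_fw(f$x, f$dims, as.integer(stride), W, b)
  list(out = fm(out, conv_out_dims(f$dims, stride)),
       cache = list(x = f$x, W = W, dims_in = f$dims, stride = stride))
}

conv3_bw <- function(cache, gout, need_gx = TRUE) {
  r <- conv3_gemm_bw(cache$x, cache$dims_in, as.integer(cache$stride),
                     cache$W, gout, need_gx)
  list(gx = if (need_gx) fm(r$gx, cache$dims_in) else NULL,
       gW = r$gW, gb = r$gb)
}

conv1_fw <- function(f, W, b) {
  out <- f$x %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = fm(out, f$dims), cache = list(x = f$x, W = W, dims = f$dims))
}

conv1_bw <- function(cache, gout) {
  list(gx = fm(gout %*% t(cache$W), cache$dims),
       gW = crossprod(cache$x, gout), gb = colSums(gout))
}

instnorm_fw <- function(f, gamma, beta, eps = 1e-5) {
  r <- instnorm_cpp_fw(f$x, gamma, beta, eps)
  list(out = fm(r$y, f$dims),
       cache = list(xhat = r$xhat, istd = r$istd, gamma = gamma, dims = f$dims))
}

instnorm_bw <- function(cache, gout) {
  r <- instnorm_cpp_bw(cache$xhat, cache$istd, cache$gamma, gout)
  list(gx = fm(r$gx, cache$dims), ggamma = r$ggamma, gbeta = r$gbeta)
}

lrelu_fw <- function(f, slope = 0.01) {
  scale <- (f$x > 0) * (1 - slope) + slope
  list(out = fm(f$x * scale, f$dims),
       cache = list(scale = scale, dims = f$dims))
}

lrelu_bw <- function(cache, gout) {
  fm(gout * cache$scale, cache$dims)
}

sigmoid_fw <- function(f) {
  y <- 1 / (1 + exp(-f$x))
  list(out = fm(y, f$dims), cache = list(y = y, dims = f$dims))
}

sigmoid_bw <- function(cache, gout) {
  fm(gout * cache$y * (1 - cache$y), cache$dims)
}

# linear voxel indices of (x,y,z) grids, column-major, x fastest
vox_index <- function(xi, yi, zi, dims) {
  xi + (yi - 1L) * dims[1] + (zi - 1L) * dims[1] * dims[2]
}

# nearest-neighbour x2 upsampling map: for each output voxel, the source
# input voxel linear index (input dims = dims_out / 2)
upsample_map <- function(dims_out) {
  din <- dims_out %/% 2L
  g <- expand.grid(x = seq_len(dims_out[1]), y = seq_len(dims_out[2]),
                   z = seq_len(dims_out[3]))
  vox_index((g$x + 1L) %/% 2L, (g$y + 1L) %/% 2L, (g$z + 1L) %/% 2L, din)
}

upsample2_fw <- function(f) {
  dims_out <- f$dims * 2L
  map <- upsample_map(dims_out)
  list(out = fm(f$x[map, , drop = FALSE], dims_out),
       cache = list(map = map, dims_in = f$dims))
}

upsample2_bw <- function(cache, gout) {
  gx <- rowsum(gout, group = cache$map, reorder = TRUE)
  fm(gx, cache$dims_in)
}

# nearest-neighbour x2 downsampling of an S x C stack (picks odd-index voxels)
nn_downsample2 <- function(f) {
  din <- f$dims
  dout <- din %/% 2L
  g <- expand.grid(x = seq_len(dout[1]), y = seq_len(dout[2]),
                   z = seq_len(dout[3]))
  idx <- vox_index(2L * g$x - 1L, 2L * g$y - 1L, 2L * g$z - 1L, din)
  fm(f$x[idx, , drop = FALSE], dout)
}

# OR-pooling (max over each 2x2x2 block) of a binary 3D mask, "any error
# here" semantics under downsampling
or_pool2 <- function(mask) {
  d <- dim(mask)
  dout <- d %/% 2L
  out <- array(0, dim = dout)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    sub <- mask[seq(1L + ox, 2L * dout[1], by = 2L),
                seq(1L + oy, 2L * dout[2], by = 2L),
                seq(1L + oz, 2L * dout[3], by = 2L)]
    out <- pmax(out, sub)
  }
  out
}

# pool a full-resolution mask down the supervision pyramid: level 1 is the
# mask itself, level j+1 is the OR-pooled level j
pool_mask_pyramid <- function(mask, dn) {
  out <- vector("list", dn)
  out[[1L]] <- mask
  if (dn > 1L) for (j in 2:dn) out[[j]] <- or_pool2(out[[j - 1L]])
  out
}

# downsample a one-hot target stack (4D array) to pyramid levels as S x C fms
target_pyramid <- function(onehot, dn) {
  d <- dim(onehot)
  f <- fm(matrix(onehot, nrow = prod(d[1:3]), ncol = d[4]), d[1:3])
  out <- vector("list", dn)
  out[[1L]] <- f
  if (dn > 1L) for (j in 2:dn) out[[j]] <- nn_downsample2(out[[j - 1L]])
  out
}
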