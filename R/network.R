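#' Network configuration
#'
#' Describes the asymmetric 3D encoder--decoder segmentation network. The
#' encoder uses `conv_per_block` 3x3x3 convolutions per resolution stage
#' (instance norm + leaky ReLU after each), downsampling by stride-2
#' convolutions; the filter count at downsampling round r is
#' \code{base_filters * 2^min(r, filter_doubling_rounds)} capped at
#' \code{filter_cap}. The decoder mirrors the encoder with nearest-neighbour
#' upsampling and skip concatenation; when \code{asymmetric = TRUE} decoder
#' blocks use half the width of their encoder mirrors. Deep-supervision heads
#' (1x1x1 convolution + sigmoid) sit on the \code{dn} highest-resolution
#' decoder stages.
#'
#' @param n_labels number of output classes N.
#' @param base_filters encoder width at full resolution.
#' @param n_down number of downsampling rounds.
#' @param filter_doubling_rounds rounds over which widths keep doubling.
#' @param filter_cap ceiling on any layer width.
#' @param dn number of deep-supervision outputs (must be <= n_down).
#' @param conv_per_block convolutions per resolution stage.
#' @param lrelu_slope negative slope of the leaky ReLU.
#' @param norm "instance" or "none".
#' @param asymmetric halve decoder widths relative to the encoder.
#' @return list of class \code{network_config}.
#' @seealso \code{\link{network_preset}} for ready-made sizes.
#' @export
network_config <- function(n_labels, base_filters = 8L, n_down = 3L,
                           filter_doubling_rounds = n_down, filter_cap = 320L,
                           dn = 3L, conv_per_block = 2L, lrelu_slope = 0.01,
                           norm = "instance", asymmetric = TRUE) {
  stopifnot(n_labels >= 2, base_filters >= 1, n_down >= 1, dn >= 1,
            conv_per_block >= 1, filter_doubling_rounds >= 1, filter_cap >= 1)
  if (dn > n_down) stop("dn must be <= n_down")
  if (!norm %in% c("instance", "none")) stop("norm must be 'instance' or 'none'")
  structure(list(n_labels = as.integer(n_labels),
                 base_filters = as.integer(base_filters),
                 n_down = as.integer(n_down),
                 filter_doubling_rounds = as.integer(filter_doubling_rounds),
                 filter_cap = as.integer(filter_cap), dn = as.integer(dn),
                 conv_per_block = as.integer(conv_per_block),
                 lrelu_slope = lrelu_slope, norm = norm,
                 asymmetric = isTRUE(asymmetric)),
            class = "network_config")
}

#' Ready-made network sizes
#'
#' \code{"desk"}: a small net for 24^3-scale phantom experiments (base 8,
#' 3 downsampling rounds, 3 supervision levels). \code{"baseline"}: standard
#' U-Net-style widths (base 32, 5 rounds, widths doubling for 3 rounds,
#' symmetric decoder). \code{"paper_scale"}: the deepened/widened variant
#' (doubling continues for 4 rounds, higher cap, asymmetric decoder), which
#' has strictly more parameters than \code{"baseline"}.
#'
#' @param name one of "desk", "baseline", "paper_scale".
#' @param n_labels number of classes (default 4).
#' @return a \code{\link{network_config}}.
#' @export
network_preset <- function(name, n_labels = 4L) {
  switch(name,
    # symmetric decoder: at width 4 the asymmetric halving would leave a
    # 2-channel full-resolution feature map, too narrow for 4-class decoding
    desk = network_config(n_labels, base_filters = 4L, n_down = 3L,
                          filter_doubling_rounds = 3L, dn = 3L,
                          asymmetric = FALSE),
    baseline = network_config(n_labels, base_filters = 32L, n_down = 5L,
                              filter_doubling_rounds = 3L, filter_cap = 320L,
                              dn = 3L, asymmetric = FALSE),
    paper_scale = network_config(n_labels, base_filters = 32L, n_down = 5L,
                                 filter_doubling_rounds = 4L, filter_cap = 512L,
                                 dn = 3L, asymmetric = TRUE),
    stop("unknown network preset: ", name))
}

enc_channels <- function(cfg, r) {
  min(cfg$base_filters * 2^min(r, cfg$filter_doubling_rounds), cfg$filter_cap)
}

dec_channels <- function(cfg, rr) {
  w <- enc_channels(cfg, rr)
  if (cfg$asymmetric) max(w %/% 2L, 2L) else w
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build (initialise) a segmentation network
#'
#' Allocates and He-initialises all parameters described by a
#' \code{\link{network_config}}. Initialisation draws from the current R RNG
#' stream, so \code{set.seed()} before building gives a reproducible network.
#'
#' @param cfg a \code{\link{network_config}}.
#' @return object of class \code{msf_network}: list with \code{cfg} and
#'   \code{params} (named list of weight matrices / vectors).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  p <- list()
  add_conv <- function(p, name, cin, cout, k) {
    p[[paste0(name, "_W")]] <- he_init(k * cin, cout, k * cin)
    p[[paste0(name, "_b")]] <- numeric(cout)
    if (cfg$norm == "instance") {
      p[[paste0(name, "_g")]] <- rep(1, cout)
      p[[paste0(name, "_be")]] <- numeric(cout)
    }
    p
  }
  for (r in 0:cfg$n_down) {
    cout <- enc_channels(cfg, r)
    for (cc in seq_len(cfg$conv_per_block)) {
      cin <- if (cc > 1L) cout else if (r == 0L) 1L else enc_channels(cfg, r - 1L)
      p <- add_conv(p, sprintf("enc%d_c%d", r, cc), cin, cout, 27L)
    }
  }
  for (rr in (cfg$n_down - 1L):0L) {
    cout <- dec_channels(cfg, rr)
    up_in <- if (rr == cfg$n_down - 1L) enc_channels(cfg, cfg$n_down)
             else dec_channels(cfg, rr + 1L)
    for (cc in seq_len(cfg$conv_per_block)) {
      cin <- if (cc == 1L) up_in + enc_channels(cfg, rr) else cout
      p <- add_conv(p, sprintf("dec%d_c%d", rr, cc), cin, cout, 27L)
    }
  }
  for (j in seq_len(cfg$dn)) {
    cin <- dec_channels(cfg, j - 1L)
    p[[sprintf("head%d_W", j)]] <- he_init(cin, cfg$n_labels, cin)
    p[[sprintf("head%d_b", j)]] <- numeric(cfg$n_labels)
  }
  structure(list(cfg = cfg, params = p), class = "msf_network")
}

#' Number of trainable parameters
#'
#' @param network an \code{msf_network} or a \code{network_config} (a
#'   throwaway network is built to count).
#' @return integer parameter count.
#' @export
count_params <- function(network) {
  if (inherits(network, "network_config")) {
    # count analytically without allocating: replicate build_network's shapes
    cfg <- network
    n <- 0
    cnt_conv <- function(cin, cout, k) k * cin * cout + cout +
      if (cfg$norm == "instance") 2 * cout else 0
    for (r in 0:cfg$n_down) {
      cout <- enc_channels(cfg, r)
      for (cc in seq_len(cfg$conv_per_block)) {
        cin <- if (cc > 1L) cout else if (r == 0L) 1L else enc_channels(cfg, r - 1L)
        n <- n + cnt_conv(cin, cout, 27L)
      }
    }
    for (rr in (cfg$n_down - 1L):0L) {
      cout <- dec_channels(cfg, rr)
      up_in <- if (rr == cfg$n_down - 1L) enc_channels(cfg, cfg$n_down)
               else dec_channels(cfg, rr + 1L)
      for (cc in seq_len(cfg$conv_per_block)) {
        cin <- if (cc == 1L) up_in + enc_channels(cfg, rr) else cout
        n <- n + cnt_conv(cin, cout, 27L)
      }
    }
    for (j in seq_len(cfg$dn))
      n <- n + dec_channels(cfg, j - 1L) * cfg$n_labels + cfg$n_labels
    return(n)
  }
  sum(vapply(network$params, length, numeric(1)))
}

#' @export
print.msf_network <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<msf_network> %d labels, base %d, %d downsampling rounds,",
                     " %d supervision heads\n"),
              cfg$n_labels, cfg$base_filters, cfg$n_down, cfg$dn))
  cat("  parameters:", format(count_params(x), big.mark = ","), "\n")
  invisible(x)
}

# one conv -> (instance norm) -> leaky ReLU unit; returns out + caches
conv_unit_fw <- function(f, p, name, stride, cfg) {
  cv <- conv3_fw(f, p[[paste0(name, "_W")]], p[[paste0(name, "_b")]], stride)
  if (cfg$norm == "instance") {
    nm <- instnorm_fw(cv$out, p[[paste0(name, "_g")]], p[[paste0(name, "_be")]])
  } else nm <- list(out = cv$out, cache = NULL)
  ac <- lrelu_fw(nm$out, cfg$lrelu_slope)
  list(out = ac$out,
       cache = list(conv = cv$cache, norm = nm$cache, act = ac$cache))
}

conv_unit_bw <- function(cache, gout, grads, name, cfg, need_gx = TRUE) {
  g <- lrelu_bw(cache$act, gout)
  if (cfg$norm == "instance") {
    nb <- instnorm_bw(cache$norm, g$x)
    grads[[paste0(name, "_g")]] <- grads[[paste0(name, "_g")]] + nb$ggamma
    grads[[paste0(name, "_be")]] <- grads[[paste0(name, "_be")]] + nb$gbeta
    g <- nb$gx
  }
  cb <- conv3_bw(cache$conv, g$x, need_gx)
  grads[[paste0(name, "_W")]] <- grads[[paste0(name, "_W")]] + cb$gW
  grads[[paste0(name, "_b")]] <- grads[[paste0(name, "_b")]] + cb$gb
  list(gx = cb$gx, grads = grads)
}

check_input_dims <- function(cfg, dims) {
  if (any(dims %% 2^cfg$n_down != 0))
    stop("input spatial size ", paste(dims, collapse = "x"),
         " is not divisible by 2^n_down = ", 2^cfg$n_down,
         "; pad the volume to a multiple before the forward pass")
}

# Forward pass. image: 3D array. Returns list(outputs = list of dn fms
# (sigmoid probabilities, level 1 at full resolution), cache or NULL).
net_forward <- function(network, image, want_cache = FALSE) {
  cfg <- network$cfg
  p <- network$params
  dims <- dim(image)
  check_input_dims(cfg, dims)
  f <- fm(matrix(as.numeric(image), ncol = 1L), dims)
  enc_out <- vector("list", cfg$n_down + 1L)
  enc_cache <- vector("list", cfg$n_down + 1L)
  for (r in 0:cfg$n_down) {
    caches <- vector("list", cfg$conv_per_block)
    for (cc in seq_len(cfg$conv_per_block)) {
      stride <- if (cc == 1L && r > 0L) 2L else 1L
      u <- conv_unit_fw(f, p, sprintf("enc%d_c%d", r, cc), stride, cfg)
      f <- u$out
      caches[[cc]] <- u$cache
    }
    enc_out[[r + 1L]] <- f
    enc_cache[[r + 1L]] <- caches
  }
  dec_out <- vector("list", cfg$n_down)        # indexed by rr + 1
  dec_cache <- vector("list", cfg$n_down)
  for (rr in (cfg$n_down - 1L):0L) {
    up <- upsample2_fw(f)
    skip <- enc_out[[rr + 1L]]
    n_up <- ncol(up$out$x)
    f <- fm(cbind(up$out$x, skip$x), up$out$dims)
    caches <- vector("list", cfg$conv_per_block)
    for (cc in seq_len(cfg$conv_per_block)) {
      u <- conv_unit_fw(f, p, sprintf("dec%d_c%d", rr, cc), 1L, cfg)
      f <- u$out
      caches[[cc]] <- u$cache
    }
    dec_out[[rr + 1L]] <- f
    dec_cache[[rr + 1L]] <- list(convs = caches, up = up$cache, n_up = n_up)
  }
  outputs <- vector("list", cfg$dn)
  head_cache <- vector("list", cfg$dn)
  for (j in seq_len(cfg$dn)) {
    hc <- conv1_fw(dec_out[[j]], p[[sprintf("head%d_W", j)]],
                   p[[sprintf("head%d_b", j)]])
    sg <- sigmoid_fw(hc$out)
    outputs[[j]] <- sg$out
    head_cache[[j]] <- list(conv = hc$cache, sig = sg$cache)
  }
  list(outputs = outputs,
       cache = if (want_cache)
         list(enc = enc_cache, dec = dec_cache, heads = head_cache) else NULL)
}

# Backward pass: gheads is a list of dn gradients (S_j x N matrices) w.r.t.
# the sigmoid outputs. Returns named list of parameter gradients.
net_backward <- function(network, cache, gheads) {
  cfg <- network$cfg
  grads <- lapply(network$params, function(q) array(0, dim = dim(q) %||% length(q)))
  grads <- lapply(grads, function(g) if (is.matrix(g)) g else as.numeric(g))
  names(grads) <- names(network$params)
  gdec <- vector("list", cfg$n_down)  # gradient at each decoder stage output
  for (j in seq_len(cfg$dn)) {
    hc <- cache$heads[[j]]
    g <- sigmoid_bw(hc$sig, gheads[[j]])
    cb <- conv1_bw(hc$conv, g$x)
    grads[[sprintf("head%d_W", j)]] <- grads[[sprintf("head%d_W", j)]] + cb$gW
    grads[[sprintf("head%d_b", j)]] <- grads[[sprintf("head%d_b", j)]] + cb$gb
    gdec[[j]] <- if (is.null(gdec[[j]])) cb$gx$x else gdec[[j]] + cb$gx$x
  }
  genc <- vector("list", cfg$n_down + 1L)  # skip + downstream grads per stage
  gbottle <- NULL
  for (rr in 0:(cfg$n_down - 1L)) {   # fine to coarse (reverse of forward)
    dc <- cache$dec[[rr + 1L]]
    g <- gdec[[rr + 1L]]
    if (is.null(g)) {
      # stage feeds only the finer stage; gradient arrived via upsample below
      stop("internal error: missing decoder gradient at stage ", rr)
    }
    gf <- fm(g, dc$convs[[cfg$conv_per_block]]$act$dims)
    for (cc in rev(seq_len(cfg$conv_per_block))) {
      r <- conv_unit_bw(dc$convs[[cc]], gf$x, grads, sprintf("dec%d_c%d", rr, cc), cfg)
      gf <- r$gx
      grads <- r$grads
    }
    g_up <- gf$x[, seq_len(dc$n_up), drop = FALSE]
    g_skip <- gf$x[, -seq_len(dc$n_up), drop = FALSE]
    genc[[rr + 1L]] <- if (is.null(genc[[rr + 1L]])) g_skip
                       else genc[[rr + 1L]] + g_skip
    gu <- upsample2_bw(dc$up, g_up)
    if (rr == cfg$n_down - 1L) {
      gbottle <- gu$x
    } else {
      gdec[[rr + 2L]] <- if (is.null(gdec[[rr + 2L]])) gu$x
                         else gdec[[rr + 2L]] + gu$x
    }
  }
  genc[[cfg$n_down + 1L]] <- gbottle
  for (r in cfg$n_down:0L) {
    ec <- cache$enc[[r + 1L]]
    gf <- genc[[r + 1L]]
    for (cc in rev(seq_len(cfg$conv_per_block))) {
      last <- (r == 0L && cc == 1L)   # input gradient is never needed
      rbk <- conv_unit_bw(ec[[cc]], gf, grads, sprintf("enc%d_c%d", r, cc),
                          cfg, need_gx = !last)
      gf <- if (last) NULL else rbk$gx$x
      grads <- rbk$grads
    }
    if (r > 0L)
      genc[[r]] <- if (is.null(genc[[r]])) gf else genc[[r]] + gf
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment an image with a trained network
#'
#' Runs a forward pass and decodes the full-resolution deep-supervision
#' output by per-voxel argmax (ties toward the lowest label index).
#'
#' @param network an \code{msf_network}.
#' @param image 3D numeric array whose axes are divisible by
#'   \code{2^n_down}.
#' @param spacing voxel spacing attached to the result.
#' @return a \code{\link{label_volume}}.
#' @export
predict_labels <- function(network, image, spacing = c(1, 1, 1)) {
  out <- net_forward(network, image)$outputs[[1L]]
  lab <- max.col(out$x, ties.method = "first") - 1L
  label_volume(array(lab, dim = out$dims), n_labels = network$cfg$n_labels,
               spacing = spacing)
}

# forward pass returning the dn-level probability pyramid (as 4D arrays)
net_prob_pyramid <- function(network, image) {
  out <- net_forward(network, image)$outputs
  lapply(out, function(f) array(f$x, dim = c(f$dims, ncol(f$x))))
}
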