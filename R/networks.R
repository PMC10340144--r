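# ---------------------------------------------------------------------------
# Network architectures: style-transfer generator G, discriminators D_A/D_B,
# and the 3D U-Net segmenter.  All are fully convolutional over channel-last
# (D, H, W, C) blocks and built on the package's autodiff ops.
# ---------------------------------------------------------------------------

#' Generator configuration
#'
#' The style-transfer generator maps a single-channel volumetric block to a
#' same-sized block in the target (P-phase) intensity style.  It consists of
#' three encoding convolutions (strides 1, 2, 2), nine residual blocks at the
#' bottleneck resolution, two stride-2 transposed-convolution decoders, and a
#' final convolution squashed to the normalized intensity range [0, 1].
#'
#' @param base_width channel count of the first encoder layer; widths double
#'   at each stride-2 encoder (`base_width = 32` for clinical blocks,
#'   4 in the desk-scale presets).
#' @param in_channels input channel count (1 for CT blocks).
#' @param n_resblocks number of residual blocks at the bottleneck.
#' @return a `generator_config` list.
#' @export
generator_config <- function(base_width = 32L, in_channels = 1L, n_resblocks = 9L) {
  stopifnot(base_width >= 1, in_channels >= 1, n_resblocks >= 1)
  structure(list(base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 n_resblocks = as.integer(n_resblocks)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Five stride-2 convolutions followed by global average pooling and a
#' sigmoid, producing one scalar score in (0, 1) per input block (1 = judged
#' real P-phase style / real annotation).
#'
#' @inheritParams generator_config
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(base_width = 32L, in_channels = 1L) {
  stopifnot(base_width >= 1, in_channels >= 1)
  structure(list(base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels)),
            class = "discriminator_config")
}

#' 3D U-Net configuration
#'
#' Four max-pooling downsamplings of stride 2 mirrored by four stride-2
#' transposed-convolution upsamplings with same-level skip concatenation.
#' Every level applies two (convolution, instance norm, leaky ReLU) blocks.
#' Input spatial extents must be divisible by 16.
#'
#' @inheritParams generator_config
#' @param out_channels number of output classes (2: portal vein, background).
#' @return a `unet_config` list.
#' @export
unet_config <- function(base_width = 32L, in_channels = 1L, out_channels = 2L) {
  stopifnot(base_width >= 1, in_channels >= 1, out_channels >= 2)
  structure(list(base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = 4L),
            class = "unet_config")
}

# --- parameter constructors -------------------------------------------------

conv_pars <- function(cin, cout, k = 3L) {
  sd <- sqrt(2 / (k^3 * cin))
  list(w = ag_param(array(stats::rnorm(k^3 * cin * cout, 0, sd),
                          dim = c(k, k, k, cin, cout))),
       b = ag_param(numeric(cout)))
}

convt_pars <- function(cin, cout, k = 3L) {
  sd <- sqrt(2 / (k^3 * cin))
  # transposed-conv weight layout: (k, k, k, Cout, Cin)
  list(w = ag_param(array(stats::rnorm(k^3 * cin * cout, 0, sd),
                          dim = c(k, k, k, cout, cin))),
       b = ag_param(numeric(cout)))
}

inorm_pars <- function(c) {
  list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)))
}

# conv + instance norm + leaky ReLU
cil_pars <- function(cin, cout) list(conv = conv_pars(cin, cout), norm = inorm_pars(cout))

cil_fwd <- function(p, x, stride = 1L) {
  h <- ag_conv3d(x, p$conv$w, p$conv$b, stride = stride, pad = 1L)
  ag_leaky_relu(ag_instance_norm(h, p$norm$gamma, p$norm$beta))
}

# Recursively collect every trainable tensor of a network.
#' @keywords internal
flatten_params <- function(x) {
  if (is_ag_tensor(x)) return(if (x$requires_grad) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, flatten_params)))
  list()
}

ensure_channel <- function(x) {
  v <- ag_val(x)
  if (length(dim(v)) == 3L) {
    dim(v) <- c(dim(v), 1L)
    if (is_ag_tensor(x)) stop("3D ag_tensor inputs must already carry a channel axis")
    return(v)
  }
  x
}

# --- generator --------------------------------------------------------------

#' Initialize generator weights
#'
#' Draws He-scaled random weights from the current RNG stream (seed with
#' [set.seed()] for reproducibility).
#'
#' @param config a [generator_config()].
#' @return a `generator` object (config + parameter tensors).
#' @export
generator_init <- function(config = generator_config()) {
  w <- config$base_width
  net <- list(
    config = config,
    e1 = cil_pars(config$in_channels, w),
    e2 = cil_pars(w, 2L * w),
    e3 = cil_pars(2L * w, 4L * w),
    res = lapply(seq_len(config$n_resblocks), function(i) {
      list(c1 = conv_pars(4L * w, 4L * w), n1 = inorm_pars(4L * w),
           c2 = conv_pars(4L * w, 4L * w), n2 = inorm_pars(4L * w))
    }),
    d1 = list(conv = convt_pars(4L * w, 2L * w), norm = inorm_pars(2L * w)),
    d2 = list(conv = convt_pars(2L * w, w), norm = inorm_pars(w)),
    out = conv_pars(w, 1L)
  )
  # small output weights keep the initial residual correction near zero
  net$out$w$value <- net$out$w$value * 0.1
  structure(net, class = "generator")
}

#' Generator forward pass
#'
#' @param net a [generator_init()] network.
#' @param x a block: (D,H,W) or (D,H,W,1) array (or tensor) of normalized
#'   intensities in [0, 1]; spatial extents must be divisible by 4.
#' @return a tensor of the same shape with values in (0, 1).
#' @export
generator_forward <- function(net, x) {
  x <- ensure_channel(x)
  dm <- dim(ag_val(x))
  if (any(dm[1:3] %% 4L != 0L))
    stop("generator input spatial dims must be divisible by 4, got ",
         paste(dm[1:3], collapse = "x"))
  h1 <- cil_fwd(net$e1, x, stride = 1L)
  h2 <- cil_fwd(net$e2, h1, stride = 2L)
  h3 <- cil_fwd(net$e3, h2, stride = 2L)
  h <- h3
  for (rb in net$res) {
    r <- ag_conv3d(h, rb$c1$w, rb$c1$b, stride = 1L, pad = 1L)
    r <- ag_leaky_relu(ag_instance_norm(r, rb$n1$gamma, rb$n1$beta))
    r <- ag_conv3d(r, rb$c2$w, rb$c2$b, stride = 1L, pad = 1L)
    r <- ag_instance_norm(r, rb$n2$gamma, rb$n2$beta)
    h <- ag_add(h, r)
  }
  s3 <- dim(ag_val(h3))[1:3]
  u1 <- ag_convt3d(h, net$d1$conv$w, net$d1$conv$b, stride = 2L, pad = 1L,
                   out_spatial = s3 * 2L)
  u1 <- ag_leaky_relu(ag_instance_norm(u1, net$d1$norm$gamma, net$d1$norm$beta))
  u2 <- ag_convt3d(u1, net$d2$conv$w, net$d2$conv$b, stride = 2L, pad = 1L,
                   out_spatial = dm[1:3])
  u2 <- ag_leaky_relu(ag_instance_norm(u2, net$d2$norm$gamma, net$d2$norm$beta))
  z <- ag_conv3d(u2, net$out$w, net$out$b, stride = 1L, pad = 1L)
  # residual output head: the transfer is a bounded intensity correction of
  # the input, so an untrained generator starts near the identity mapping
  ag_add(x, ag_mul(ag_tanh(z), 0.5))
}

# --- discriminator ----------------------------------------------------------

#' Initialize discriminator weights
#'
#' Plain stride-2 convolutions with leaky ReLU, no normalization layers:
#' the discriminators must be able to judge global intensity style, which
#' instance normalization would remove.
#'
#' @param config a [discriminator_config()].
#' @return a `discriminator` object.
#' @export
discriminator_init <- function(config = discriminator_config()) {
  w <- config$base_width
  structure(list(
    config = config,
    c1 = conv_pars(config$in_channels, w),
    c2 = conv_pars(w, 2L * w),
    c3 = conv_pars(2L * w, 4L * w),
    c4 = conv_pars(4L * w, 8L * w),
    c5 = conv_pars(8L * w, 1L)
  ), class = "discriminator")
}

#' Discriminator forward pass
#'
#' Five stride-2 convolutions, spatial average pooling, sigmoid.
#'
#' @param net a [discriminator_init()] network.
#' @param x a (D,H,W) or (D,H,W,C) block or probability channel.
#' @return a scalar tensor strictly inside (0, 1).
#' @export
discriminator_forward <- function(net, x) {
  x <- ensure_channel(x)
  dm <- dim(ag_val(x))
  if (dm[4] != net$config$in_channels)
    stop("discriminator expects ", net$config$in_channels, " channel(s), got ", dm[4])
  h <- ag_leaky_relu(ag_conv3d(x, net$c1$w, net$c1$b, stride = 2L, pad = 1L))
  h <- ag_leaky_relu(ag_conv3d(h, net$c2$w, net$c2$b, stride = 2L, pad = 1L))
  h <- ag_leaky_relu(ag_conv3d(h, net$c3$w, net$c3$b, stride = 2L, pad = 1L))
  h <- ag_leaky_relu(ag_conv3d(h, net$c4$w, net$c4$b, stride = 2L, pad = 1L))
  h <- ag_conv3d(h, net$c5$w, net$c5$b, stride = 2L, pad = 1L)
  ag_sigmoid(ag_mean(h))
}

# --- 3D U-Net ---------------------------------------------------------------

#' Initialize 3D U-Net weights
#' @param config a [unet_config()].
#' @return a `unet` object.
#' @export
unet_init <- function(config = unet_config()) {
  w <- config$base_width
  widths <- w * 2L^(0:4)                       # encoder widths + bottleneck
  enc <- vector("list", 4L)
  cin <- config$in_channels
  for (i in 1:4) {
    enc[[i]] <- list(a = cil_pars(cin, widths[i]), b = cil_pars(widths[i], widths[i]))
    cin <- widths[i]
  }
  bott <- list(a = cil_pars(widths[4], widths[5]), b = cil_pars(widths[5], widths[5]))
  dec <- vector("list", 4L)
  for (i in 4:1) {
    ch <- widths[i + 1L]                       # channels entering this decoder
    dec[[i]] <- list(up = convt_pars(ch, widths[i]),
                     a = cil_pars(2L * widths[i], widths[i]),
                     b = cil_pars(widths[i], widths[i]))
  }
  out <- conv_pars(widths[1], config$out_channels, k = 1L)
  # class-prior bias: the portal vein fills ~1% of a block, so start the
  # softmax head strongly in favor of background to avoid wasting early
  # updates on suppressing foreground everywhere
  out$b$value <- c(2, rep(-2, config$out_channels - 1L))
  structure(list(config = config, enc = enc, bott = bott, dec = dec, out = out),
            class = "unet")
}

#' 3D U-Net forward pass
#'
#' @param net a [unet_init()] network.
#' @param x a (D,H,W) or (D,H,W,1) block of normalized intensities; every
#'   spatial extent must be divisible by 16.
#' @param trace_shapes if TRUE, attach the encoder/decoder feature shapes as
#'   attribute `"shapes"` for architecture introspection.
#' @return a probability-map tensor (D,H,W,C): per-voxel softmax over classes.
#' @export
unet_forward <- function(net, x, trace_shapes = FALSE) {
  x <- ensure_channel(x)
  dm <- dim(ag_val(x))
  ax <- c("depth", "height", "width")
  bad <- which(dm[1:3] %% 16L != 0L)
  if (length(bad))
    stop("U-Net input ", ax[bad[1]], " (", dm[bad[1]], ") is not divisible by 16")
  skips <- vector("list", 4L)
  shapes <- list(enc = list(), dec = list())
  h <- x
  for (i in 1:4) {
    h <- cil_fwd(net$enc[[i]]$a, h)
    h <- cil_fwd(net$enc[[i]]$b, h)
    skips[[i]] <- h
    shapes$enc[[i]] <- dim(ag_val(h))
    h <- ag_maxpool3d(h)
  }
  h <- cil_fwd(net$bott$a, h)
  h <- cil_fwd(net$bott$b, h)
  for (i in 4:1) {
    target <- dim(ag_val(skips[[i]]))[1:3]
    h <- ag_convt3d(h, net$dec[[i]]$up$w, net$dec[[i]]$up$b,
                    stride = 2L, pad = 1L, out_spatial = target)
    h <- ag_concat_c(h, skips[[i]])
    h <- cil_fwd(net$dec[[i]]$a, h)
    h <- cil_fwd(net$dec[[i]]$b, h)
    shapes$dec[[i]] <- dim(ag_val(h))
  }
  logits <- ag_conv3d(h, net$out$w, net$out$b, stride = 1L, pad = 0L)
  p <- ag_softmax_c(logits)
  if (trace_shapes) attr(p, "shapes") <- shapes
  p
}

#' Count trainable parameters of a network
#' @param net a generator, discriminator, or unet object.
#' @return integer number of scalar parameters.
#' @export
n_parameters <- function(net) {
  sum(vapply(flatten_params(net), function(p) length(p$value), numeric(1)))
}
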