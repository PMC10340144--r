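#' @useDynLib portalseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# A "tensor" is an environment holding $value (numeric array), $grad
# (accumulated during backward), and, while a tape is active, a $backward
# closure mapping the output gradient to a list of parent gradients.  Ops
# executed outside a tape (inference) only compute values.  Volumetric
# tensors use channel-last layout (D, H, W, C).
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L

ag_tape_start <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

is_ag_tensor <- function(x) inherits(x, "ag_tensor")

ag_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$needs_grad <- requires_grad
  e$parents <- list()
  e$backward <- NULL
  class(e) <- "ag_tensor"
  e
}

ag_param <- function(value) ag_tensor(value, requires_grad = TRUE)

as_tensor <- function(x) if (is_ag_tensor(x)) x else ag_tensor(x)

ag_val <- function(x) if (is_ag_tensor(x)) x$value else x

ag_detach <- function(x) ag_tensor(ag_val(x))

# Create an op node.  `backward(g)` must return a list of gradients aligned
# with `parents`.  Only recorded when a tape is active and some parent needs
# gradients; otherwise a plain constant tensor is returned.
ag_op <- function(value, parents, backward) {
  needs <- !is.null(.ag$tape) &&
    any(vapply(parents, function(p) isTRUE(p$needs_grad), logical(1)))
  node <- ag_tensor(value)
  if (needs) {
    node$needs_grad <- TRUE
    node$parents <- parents
    node$backward <- backward
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- node
    .ag$n <- n
  }
  node
}

# Reverse sweep over the tape from `root` (a scalar tensor).
ag_backward <- function(root) {
  stopifnot(is_ag_tensor(root), length(root$value) == 1L)
  if (is.null(.ag$tape)) stop("ag_backward called with no active tape")
  root$grad <- 1
  for (i in seq(.ag$n, 1L)) {
    node <- .ag$tape[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!isTRUE(p$needs_grad)) next
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- elementwise / reduction ops -------------------------------------------

# Sum gradient down to a scalar when the input was a broadcast scalar.
bcast_grad <- function(g, v) if (length(v) == 1L && length(g) > 1L) sum(g) else g

ag_add <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  va <- a$value; vb <- b$value
  ag_op(va + vb, list(a, b),
        function(g) list(bcast_grad(g, va), bcast_grad(g, vb)))
}

ag_sub <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  va <- a$value; vb <- b$value
  ag_op(va - vb, list(a, b),
        function(g) list(bcast_grad(g, va), bcast_grad(-g, vb)))
}

ag_mul <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  va <- a$value; vb <- b$value
  ag_op(va * vb, list(a, b),
        function(g) list(bcast_grad(g * vb, va), bcast_grad(g * va, vb)))
}

ag_div <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  va <- a$value; vb <- b$value
  ag_op(va / vb, list(a, b),
        function(g) list(bcast_grad(g / vb, va), bcast_grad(-g * va / (vb * vb), vb)))
}

ag_neg <- function(a) {
  a <- as_tensor(a)
  ag_op(-a$value, list(a), function(g) list(-g))
}

ag_square <- function(a) {
  a <- as_tensor(a)
  va <- a$value
  ag_op(va * va, list(a), function(g) list(2 * va * g))
}

ag_sum <- function(a) {
  a <- as_tensor(a)
  va <- a$value
  ag_op(sum(va), list(a), function(g) list(array(g, dim = dim(va) %||% length(va))))
}

ag_mean <- function(a) {
  a <- as_tensor(a)
  va <- a$value
  n <- length(va)
  ag_op(sum(va) / n, list(a),
        function(g) list(array(g / n, dim = dim(va) %||% length(va))))
}

ag_log <- function(a, eps = 1e-7) {
  a <- as_tensor(a)
  vc <- pmax(a$value, eps)
  ag_op(log(vc), list(a), function(g) list(g / vc))
}

ag_sigmoid <- function(a) {
  a <- as_tensor(a)
  s <- 1 / (1 + exp(-a$value))
  ag_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(a) {
  a <- as_tensor(a)
  t <- tanh(a$value)
  ag_op(t, list(a), function(g) list(g * (1 - t * t)))
}

ag_leaky_relu <- function(a, slope = 0.2) {
  a <- as_tensor(a)
  va <- a$value
  wgt <- slope + (1 - slope) * (va > 0)
  ag_op(va * wgt, list(a), function(g) list(g * wgt))
}

ag_relu <- function(a) ag_leaky_relu(a, slope = 0)

# Smooth L1 as used by the identity losses: d^2 where |d| < 1, |d| - 0.5
# otherwise; reduction "sum" (the printed form) or "mean" (per element).
ag_smooth_l1 <- function(a, b, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  a <- as_tensor(a); b <- as_tensor(b)
  d <- a$value - b$value
  quad <- abs(d) < 1
  elt <- ifelse(quad, d * d, abs(d) - 0.5)
  n <- if (reduction == "mean") length(d) else 1L
  val <- sum(elt) / n
  ag_op(val, list(a, b), function(g) {
    dd <- ifelse(quad, 2 * d, sign(d)) * (g / n)
    list(dd, -dd)
  })
}

# --- shape ops --------------------------------------------------------------

# Softmax over the channel (last) axis of a (D,H,W,C) array.
ag_softmax_c <- function(a) {
  a <- as_tensor(a)
  va <- a$value
  dm <- dim(va)
  C <- dm[4]
  m <- matrix(va, ncol = C)
  mx <- m[, 1L]
  for (j in seq_len(C)[-1L]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  s <- e / rowSums(e)
  val <- array(s, dim = dm)
  ag_op(val, list(a), function(g) {
    gm <- matrix(g, ncol = C)
    dot <- rowSums(gm * s)
    list(array(s * (gm - dot), dim = dm))
  })
}

ag_concat_c <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:3] == db[1:3]))
  val <- array(c(a$value, b$value), dim = c(da[1:3], da[4] + db[4]))
  na <- length(a$value)
  ag_op(val, list(a, b), function(g) {
    list(array(g[seq_len(na)], dim = da),
         array(g[-seq_len(na)], dim = db))
  })
}

# Select channels `ch` from a (D,H,W,C) array (keeps 4th axis).
ag_slice_c <- function(a, ch) {
  a <- as_tensor(a)
  va <- a$value
  dm <- dim(va)
  val <- va[, , , ch, drop = FALSE]
  ag_op(val, list(a), function(g) {
    gx <- array(0, dim = dm)
    gx[, , , ch] <- g
    list(gx)
  })
}

# --- neural-network ops -----------------------------------------------------

ag_conv3d <- function(x, w, b, stride = 1L, pad = 1L) {
  x <- as_tensor(x)
  vx <- x$value; vw <- w$value
  need_gx <- isTRUE(x$needs_grad)
  y <- cpp_conv3d_fwd(vx, dim(vx), vw, dim(vw), b$value, stride, pad)
  ag_op(y, list(x, w, b), function(g) {
    gr <- cpp_conv3d_bwd(vx, dim(vx), vw, dim(vw), g, stride, pad, need_gx)
    list(gr$gx, gr$gw, gr$gb)
  })
}

ag_convt3d <- function(x, w, b, stride, pad, out_spatial) {
  x <- as_tensor(x)
  vx <- x$value; vw <- w$value
  out_spatial <- as.integer(out_spatial)
  y <- cpp_convt3d_fwd(vx, dim(vx), vw, dim(vw), b$value, stride, pad, out_spatial)
  ag_op(y, list(x, w, b), function(g) {
    gr <- cpp_convt3d_bwd(vx, dim(vx), vw, dim(vw), g, out_spatial, stride, pad)
    list(gr$gu, gr$gw, gr$gb)
  })
}

ag_maxpool3d <- function(x) {
  x <- as_tensor(x)
  vx <- x$value
  fw <- cpp_maxpool3d_fwd(vx, dim(vx))
  ag_op(fw$y, list(x), function(g) {
    gx <- cpp_maxpool3d_bwd(g, fw$idx, length(vx))
    dim(gx) <- dim(vx)
    list(gx)
  })
}

# Instance normalization over the spatial axes of (D,H,W,C), with per-channel
# affine parameters gamma/beta (length-C vectors).
ag_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_tensor(x)
  vx <- x$value
  dm <- dim(vx)
  n <- prod(dm[1:3]); C <- dm[4]
  m <- matrix(vx, nrow = n, ncol = C)
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu * mu
  sd_inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2L, mu), 2L, sd_inv, `*`)
  y <- sweep(sweep(xhat, 2L, gamma$value, `*`), 2L, beta$value, `+`)
  ag_op(array(y, dim = dm), list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = n, ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2L, gamma$value, `*`)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), `*`)
    gx <- sweep(t1 - t2, 2L, sd_inv, `*`)
    list(array(gx, dim = dm), dgamma, dbeta)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
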