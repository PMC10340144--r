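# Independent oracles used across the suite.  All are deliberately naive
# (plain loops, double precision) so they share no code with the package's
# compiled kernels.

pv <- asNamespace("portalseg")

# Direct-summation 3D convolution, channel-last (D,H,W,C), weights
# (K,K,K,Cin,Cout).
naive_conv3d <- function(x, w, b, stride, pad) {
  dmx <- dim(x); K <- dim(w)[1]; Cin <- dim(w)[4]; Cout <- dim(w)[5]
  os <- (dmx[1:3] + 2 * pad - K) %/% stride + 1
  y <- array(0, c(os, Cout))
  for (co in 1:Cout) for (wo in 1:os[3]) for (ho in 1:os[2]) for (do in 1:os[1]) {
    s <- b[co]
    for (ci in 1:Cin) for (kw in 1:K) for (kh in 1:K) for (kd in 1:K) {
      d0 <- (do - 1) * stride - pad + kd
      h0 <- (ho - 1) * stride - pad + kh
      w0 <- (wo - 1) * stride - pad + kw
      if (d0 >= 1 && d0 <= dmx[1] && h0 >= 1 && h0 <= dmx[2] && w0 >= 1 && w0 <= dmx[3])
        s <- s + x[d0, h0, w0, ci] * w[kd, kh, kw, ci, co]
    }
    y[do, ho, wo, co] <- s
  }
  y
}

# Exhaustive per-voxel evaluation of the pseudo-label rule.
naive_pseudo_label <- function(pA, pAtoV, trueV, l1, l2) {
  out <- array(0, dim = dim(trueV))
  for (i in seq_along(trueV)) {
    a <- pA[i] != 0; b <- pAtoV[i] != 0; t <- trueV[i] != 0
    out[i] <- l1 * (a && b) + l1 * t + (l2 - 2 * l1) * (a && b && t)
  }
  out
}

# Voxel-loop confusion counts.
naive_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] != 0; t <- truth[i] != 0
    if (p && t) tp <- tp + 1L else if (!p && !t) tn <- tn + 1L
    else if (p) fp <- fp + 1L else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Central finite-difference gradient of scalar-valued fn at x (element
# subset), fn operating on plain arrays in double precision.
fd_grad <- function(fn, x, idx = seq_along(x), h = 1e-6) {
  g <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

# Autodiff gradient of fn(tensor) -> scalar tensor w.r.t. x.
ag_grad <- function(fn, x) {
  pv$ag_tape_start()
  xt <- pv$ag_tensor(x)
  xt$needs_grad <- TRUE
  out <- fn(xt)
  pv$ag_backward(out)
  g <- xt$grad
  pv$ag_tape_stop()
  g
}

# Tiny training item on a 16^3 grid (block divisible by 16) for fast
# training-loop tests.
tiny_item <- function(seed = 1L) {
  p <- phantom_params(grid_shape = c(16L, 16L, 16L), n_branches = 1L,
                      vessel_radius_range = c(1.5, 2), interphase_shift = 1,
                      interphase_warp_amplitude = 0.5, seed = seed)
  case <- generate_phantom(p)
  phantom_training_item(case, "E", c(16L, 16L, 16L))
}

tiny_config <- function(variant = "full", seed = 1L, epochs = 1L, ...) {
  train_config(phase = "E", variant = variant, desk_scale = TRUE,
               block_shape = c(16L, 16L, 16L), epochs = epochs, seed = seed, ...)
}
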