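# The conv kernels run their GEMMs in single precision, so comparisons
# against the double-precision direct-summation oracle use ~1e-4 relative
# tolerances; pure-R ops are checked to much tighter bounds.

test_that("conv3d forward matches direct summation for both strides", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 4 * 2), c(6, 5, 4, 2))
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  for (s in 1:2) {
    got <- pv$cpp_conv3d_fwd(x, dim(x), w, dim(w), b, s, 1L)
    want <- naive_conv3d(x, w, b, s, 1L)
    expect_equal(dim(got), dim(want))
    expect_lt(max(abs(got - want)), 1e-4)
  }
})

test_that("conv3d gradients match finite differences of the double oracle", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  w <- array(rnorm(27 * 2 * 2), c(3, 3, 3, 2, 2))
  b <- rnorm(2)
  gy <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  gr <- pv$cpp_conv3d_bwd(x, dim(x), w, dim(w), gy, 1L, 1L, TRUE)
  fx <- function(xx) sum(naive_conv3d(xx, w, b, 1L, 1L) * gy)
  idx <- seq(1, length(x), by = 7)
  expect_lt(max(abs(gr$gx[idx] - fd_grad(fx, x, idx))), 1e-3)
  fw <- function(ww) sum(naive_conv3d(x, array(ww, dim(w)), b, 1L, 1L) * gy)
  idxw <- seq(1, length(w), by = 11)
  expect_lt(max(abs(gr$gw[idxw] - fd_grad(fw, w, idxw))), 1e-3)
  fb <- function(bb) sum(naive_conv3d(x, w, bb, 1L, 1L) * gy)
  expect_lt(max(abs(gr$gb - fd_grad(fb, b))), 1e-3)
})

test_that("transposed conv equals a flipped-kernel convolution at stride 1", {
  set.seed(3)
  u <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  w <- array(rnorm(27 * 3 * 2), c(3, 3, 3, 3, 2))   # (k,k,k,Cout,Cin)
  v <- pv$cpp_convt3d_fwd(u, dim(u), w, dim(w), numeric(3), 1L, 1L,
                          c(4L, 4L, 4L))
  wf <- array(0, c(3, 3, 3, 2, 3))                  # flipped, (k,k,k,Cin,Cout)
  for (kd in 1:3) for (kh in 1:3) for (kw in 1:3) for (co in 1:3) for (ci in 1:2)
    wf[4 - kd, 4 - kh, 4 - kw, ci, co] <- w[kd, kh, kw, co, ci]
  want <- naive_conv3d(u, wf, numeric(3), 1L, 1L)
  expect_lt(max(abs(v - want)), 1e-4)
})

test_that("transposed conv forward/backward satisfy the adjoint identity", {
  set.seed(4)
  u <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  outsp <- c(6L, 6L, 4L)
  v0 <- pv$cpp_convt3d_fwd(u, dim(u), w, dim(w), numeric(2), 2L, 1L, outsp)
  gv <- array(rnorm(length(v0)), dim(v0))
  bw <- pv$cpp_convt3d_bwd(u, dim(u), w, dim(w), gv, outsp, 2L, 1L)
  expect_lt(abs(sum(v0 * gv) - sum(u * bw$gu)) / abs(sum(v0 * gv)), 1e-4)
})

test_that("max pooling picks window maxima and routes gradients to them", {
  set.seed(5)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  fw <- pv$cpp_maxpool3d_fwd(x, dim(x))
  want <- array(0, c(2, 2, 2, 2))
  for (c in 1:2) for (w0 in 1:2) for (h in 1:2) for (d in 1:2)
    want[d, h, w0, c] <- max(x[(2*d-1):(2*d), (2*h-1):(2*h), (2*w0-1):(2*w0), c])
  expect_equal(array(fw$y, dim(want)), want)
  g <- ag_grad(function(t) pv$ag_sum(pv$ag_square(pv$ag_maxpool3d(t))), x)
  gn <- fd_grad(function(xx) {
    f <- pv$cpp_maxpool3d_fwd(xx, dim(xx)); sum(f$y^2)
  }, x)
  expect_lt(max(abs(g - gn)), 1e-4)
})

test_that("instance norm standardizes per channel and backpropagates", {
  set.seed(6)
  x <- array(rnorm(4 * 4 * 4 * 2, mean = 3, sd = 2), c(4, 4, 4, 2))
  gam <- pv$ag_param(c(1, 1)); bet <- pv$ag_param(c(0, 0))
  y <- pv$ag_val(pv$ag_instance_norm(x, gam, bet))
  for (c in 1:2) {
    expect_lt(abs(mean(y[, , , c])), 1e-8)
    expect_lt(abs(sqrt(mean(y[, , , c]^2)) - 1), 1e-3)  # population sd
  }
  g <- ag_grad(function(t) pv$ag_sum(pv$ag_square(pv$ag_instance_norm(t, gam, bet))), x)
  gn <- fd_grad(function(xx)
    sum(pv$ag_val(pv$ag_instance_norm(xx, gam, bet))^2), x, h = 1e-5)
  expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-3)
})

test_that("channel softmax produces simplex outputs with correct gradients", {
  set.seed(7)
  x <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  s <- pv$ag_val(pv$ag_softmax_c(x))
  sums <- apply(s, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  g <- ag_grad(function(t) pv$ag_sum(pv$ag_square(pv$ag_softmax_c(t))), x)
  gn <- fd_grad(function(xx) sum(pv$ag_val(pv$ag_softmax_c(xx))^2), x)
  expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-6)
})

test_that("the tape accumulates gradients through shared subexpressions", {
  x <- array(c(1, 2, 3, 4), c(2, 2))
  g <- ag_grad(function(t) {
    y <- pv$ag_mul(t, t)                     # x^2
    pv$ag_add(pv$ag_sum(y), pv$ag_sum(pv$ag_mul(y, 3)))   # 4 * sum(x^2)
  }, x)
  expect_equal(g, 8 * x)
})

test_that("constant subgraphs are not recorded and need no gradients", {
  pv$ag_tape_start()
  a <- pv$ag_tensor(matrix(1, 2, 2))
  b <- pv$ag_mul(a, 2)                       # pure constants
  expect_null(b$backward)
  pv$ag_tape_stop()
})
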