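test_that("identity losses follow the piecewise closed form", {
  a <- array(0.5, c(4, 4, 4))
  z <- array(0, c(4, 4, 4))
  n <- 64
  expect_equal(identity_loss_image(a, a), 0)
  # quadratic branch: diff 0.5 -> 0.25 per voxel
  expect_equal(identity_loss_image(a, z, reduction = "sum"), 0.25 * n)
  # linear branch: diff 2 -> 1.5 per voxel
  expect_equal(identity_loss_image(array(2, dim(a)), z, reduction = "sum"), 1.5 * n)
  expect_error(identity_loss_image(a, array(0, c(2, 2, 2))), "shape")
  # prediction variant sums over classes and voxels and is symmetric
  p <- array(0.4, c(2, 2, 2, 2)); q <- array(0.5, c(2, 2, 2, 2))
  expect_equal(identity_loss_pred(p, q, reduction = "sum"), 0.01 * 2 * 8)
  expect_equal(identity_loss_pred(p, q), identity_loss_pred(q, p))
  expect_equal(identity_loss_pred(p, p), 0)
})

test_that("adversarial losses are negative log scores", {
  g <- generator_adversarial_losses(1, 1)
  expect_equal(g$g_img, 0, tolerance = 1e-6)
  expect_equal(generator_adversarial_losses(0.5, 1)$g_img, -log(0.5))
  expect_equal(generator_adversarial_losses(exp(-2), 1)$g_img, 2)
  # clamping keeps a zero score finite
  expect_true(is.finite(generator_adversarial_losses(0, 1)$g_img))
})

test_that("discriminator loss is mean binary cross-entropy over items", {
  expect_equal(discriminator_loss(list(1), list(0)), 0, tolerance = 1e-6)
  expect_equal(discriminator_loss(list(0.5), list(0.5)), -log(0.5))
  set.seed(3)
  r <- runif(4, 0.05, 0.95); f <- runif(3, 0.05, 0.95)
  want <- (sum(-log(r)) + sum(-log(1 - f))) / 7
  expect_equal(discriminator_loss(as.list(r), as.list(f)), want)
  expect_error(discriminator_loss(list(), list()), "empty")
})

test_that("consistency loss is the per-class voxel mean of squared diffs", {
  p <- array(0.4, c(2, 2, 2, 2)); q <- array(0.5, c(2, 2, 2, 2))
  expect_equal(consistency_loss(p, q), 2 * 0.01)
  expect_equal(consistency_loss(p, q), consistency_loss(q, p))
  expect_equal(consistency_loss(p, p), 0)
})

test_that("supervised cross-entropy matches the log-likelihood oracle", {
  t <- array(c(1, 0, 0, 1, 1, 0, 0, 0), c(2, 2, 2))
  onehot <- array(c(1 - t, t), c(2, 2, 2, 2))
  expect_equal(supervised_ce_loss(onehot, t), 0, tolerance = 1e-5)
  u <- array(0.5, c(2, 2, 2, 2))
  expect_equal(supervised_ce_loss(u, t), -log(0.5))
  set.seed(4)
  pfg <- array(runif(8, 0.05, 0.95), c(2, 2, 2))
  p <- array(c(1 - pfg, pfg), c(2, 2, 2, 2))
  want <- -mean(ifelse(t == 1, log(pfg), log(1 - pfg)))
  expect_equal(supervised_ce_loss(p, t), want)
})

test_that("soft Dice loss matches direct evaluation of its definition", {
  t <- array(c(rep(1, 4), rep(0, 23)), c(3, 3, 3))
  exact <- array(c(1 - t, t), c(3, 3, 3, 2))
  expect_equal(soft_dice_loss(exact, t), 0, tolerance = 1e-6)
  # disjoint prediction and label: loss 1 per class
  disj <- array(c(t, 1 - t), c(3, 3, 3, 2))
  expect_equal(soft_dice_loss(disj, t), 2, tolerance = 1e-6)
  set.seed(5)
  pfg <- array(runif(27), c(3, 3, 3))
  p <- array(c(1 - pfg, pfg), c(3, 3, 3, 2))
  q <- array(runif(27), c(3, 3, 3))
  want <- 0
  for (ch in 1:2) {
    pc <- if (ch == 1) 1 - pfg else pfg
    qc <- if (ch == 1) 1 - q else q
    want <- want + 1 - (2 * sum(pc * qc) + 1e-7) / (sum(pc^2) + sum(qc^2) + 1e-7)
  }
  expect_equal(soft_dice_loss(p, q), want)
  # symmetric in (p, q) and bounded by the class count
  expect_equal(soft_dice_loss(array(c(1 - q, q), c(3, 3, 3, 2)), pfg), {
    w2 <- 0
    for (ch in 1:2) {
      pc <- if (ch == 1) 1 - q else q
      qc <- if (ch == 1) 1 - pfg else pfg
      w2 <- w2 + 1 - (2 * sum(pc * qc) + 1e-7) / (sum(pc^2) + sum(qc^2) + 1e-7)
    }
    w2
  })
  expect_lte(soft_dice_loss(p, q), 2)
  expect_gte(soft_dice_loss(p, q), 0)
})

test_that("the weighted total matches the published weight defaults", {
  bl <- total_loss(1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(bl$total, 5 + 5 + 0.01 + 0.01 + 1 + 10 + 5 + 5)
  zero <- total_loss(0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(zero$total, 0)
  # linearity in a single term's weight
  w2 <- loss_weights(omega6 = 20)
  only_ce1 <- total_loss(0, 0, 0, 0, 0, 1, 0, 0, w = w2)
  expect_equal(only_ce1$total, 2 * total_loss(0, 0, 0, 0, 0, 1, 0, 0)$total)
  expect_error(total_loss(NaN, 0, 0, 0, 0, 0, 0, 0), "iden_img")
})

test_that("loss gradients agree with finite differences on 2x2x2 toys", {
  set.seed(6)
  q <- array(runif(16, 0.1, 0.9), c(2, 2, 2, 2))
  t <- array(rbinom(8, 1, 0.5), c(2, 2, 2))
  pl <- array(runif(8), c(2, 2, 2))
  cases <- list(
    list(f = function(x) identity_loss_pred(x, q), x = q + 0.1),
    list(f = function(x) consistency_loss(x, q), x = q + 0.05),
    list(f = function(x) supervised_ce_loss(x, t), x = q),
    list(f = function(x) soft_dice_loss(x, pl), x = q)
  )
  for (cs in cases) {
    g <- ag_grad(function(tn) {
      r <- cs$f(tn)
      if (pv$is_ag_tensor(r)) r else pv$ag_tensor(r)
    }, cs$x)
    gn <- fd_grad(function(xx) cs$f(xx), cs$x)
    expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-3)
  }
})

test_that("every loss is nonnegative and zero at its identity configuration", {
  set.seed(8)
  p <- array(runif(16, 0.05, 0.95), c(2, 2, 2, 2))
  t <- array(rbinom(8, 1, 0.5), c(2, 2, 2))
  expect_gte(identity_loss_image(p, 0 * p), 0)
  expect_gte(consistency_loss(p, 0 * p + 0.5), 0)
  expect_gte(supervised_ce_loss(p, t), 0)
  expect_gte(soft_dice_loss(p, t * 1), 0)
  expect_equal(identity_loss_image(p, p), 0)
  expect_equal(consistency_loss(p, p), 0)
})
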