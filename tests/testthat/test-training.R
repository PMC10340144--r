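test_that("training configuration applies phase-specific defaults", {
  ch <- train_config(phase = "H")
  ce <- train_config(phase = "E")
  expect_equal(ch$epochs, 50L)
  expect_equal(ce$epochs, 40L)
  expect_equal(ch$lambda$lambda1, 0.1)
  expect_equal(ce$lambda$lambda1, 0.7)
  expect_equal(ch$learning_rate, 0.001)
  expect_equal(ch$block_shape, c(32L, 128L, 128L))
  expect_error(train_config(epochs = 0))
})

test_that("fold splits are disjoint, subject-level, and exhaustive", {
  ids <- sprintf("case%02d", 1:12)
  folds <- make_folds(ids, 3, seed = 5)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_identical(make_folds(ids, 3, seed = 5), folds)
})

test_that("a training step is bit-reproducible for a fixed seed", {
  run_once <- function() {
    set.seed(77)
    cfg <- tiny_config(seed = 77)
    models <- init_models(cfg)
    item <- tiny_item(seed = 77)
    opt <- portalseg:::new_opt_state()
    train_step(models, list(item), cfg, opt)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(unlist(a[1:9]), unlist(b[1:9]))
})

test_that("the joint objective decreases when overfitting one batch", {
  # adversarial weights off and discriminators frozen: the remaining terms
  # must shrink over 50 repeated steps on the same batch
  set.seed(21)
  cfg <- tiny_config(seed = 21,
                     weights = loss_weights(omega3 = 0, omega4 = 0),
                     freeze_discriminators = TRUE)
  models <- init_models(cfg)
  item <- tiny_item(seed = 21)
  opt <- portalseg:::new_opt_state()
  first <- train_step(models, list(item), cfg, opt)
  for (i in 1:48) invisible(train_step(models, list(item), cfg, opt))
  last <- train_step(models, list(item), cfg, opt)
  expect_lt(last$total, first$total)
  expect_true(is.finite(last$total))
})

test_that("pseudo labels tighten toward trueV on shift-free phantoms", {
  # with no inter-phase shift the correct-label region should grow to cover
  # True^V as predictions improve
  frac_l2 <- function(seed) {
    set.seed(seed)
    p <- phantom_params(grid_shape = c(16, 16, 16), n_branches = 1,
                        interphase_shift = 0, interphase_warp_amplitude = 0,
                        seed = seed)
    item <- phantom_training_item(generate_phantom(p), "E", c(16L, 16L, 16L))
    cfg <- tiny_config(seed = seed)
    models <- init_models(cfg)
    opt <- portalseg:::new_opt_state()
    frac <- function() {
      pA <- binarize_prediction(pv$ag_val(unet_forward(models$unet, item$iA)))
      pAV <- binarize_prediction(pv$ag_val(unet_forward(
        models$unet, pv$ag_val(generator_forward(models$gen, item$iA)))))
      lab <- construct_pseudo_label(pA, pAV, item$trueV, cfg$lambda)
      sum(lab == cfg$lambda$lambda2) / max(sum(item$trueV), 1)
    }
    f0 <- frac()
    for (i in 1:30) invisible(train_step(models, list(item), cfg, opt))
    c(before = f0, after = frac())
  }
  res <- vapply(c(3, 5), frac_l2, numeric(2))
  expect_true(all(res["after", ] >= res["before", ]))
  expect_gt(mean(res["after", ]), 0.5)
})

test_that("prediction composes binarization with the segmenter", {
  set.seed(30)
  cfg <- tiny_config(variant = "baseline", seed = 30)
  models <- init_models(cfg)
  item <- tiny_item(seed = 30)
  m <- predict_mask(models, item$iA)
  expect_equal(dim(m), dim(item$iA))
  expect_type(m, "logical")
  expect_identical(m, binarize_prediction(pv$ag_val(unet_forward(models$unet, item$iA))))
})

test_that("fit runs cross-validation with checkpointing and reload", {
  coh <- generate_cohort(6, phantom_params(grid_shape = c(16, 16, 16),
                                           n_branches = 1, seed = 1), seed = 40)
  cfg <- tiny_config(variant = "baseline", seed = 40, epochs = 2L)
  f <- fit(coh, cfg, n_folds = 3L, fold_subset = 1L)
  res <- f$folds[[1]]
  expect_s3_class(res$checkpoint, "pvseg_checkpoint")
  expect_length(res$test_ids, 2)
  # no test subject appears in its fold's training set
  expect_length(intersect(res$test_ids, f$split[[1]]$train), 0)
  expect_true(all(is.finite(res$log$total)))
  # checkpoint reload reproduces the forward pass bit-identically
  models <- load_models(res$checkpoint)
  item <- phantom_training_item(coh[[res$test_ids[1]]], "E", cfg$block_shape)
  p1 <- pv$ag_val(unet_forward(models$unet, item$iA))
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(res$checkpoint, tmp)
  models2 <- load_models(load_checkpoint(tmp))
  p2 <- pv$ag_val(unet_forward(models2$unet, item$iA))
  expect_identical(p1, p2)
  rep <- evaluate_checkpoint(res$checkpoint, coh, res$test_ids)
  expect_equal(nrow(rep), 2)
})
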