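# ---------------------------------------------------------------------------
# Joint optimization of the style-transfer generator, the 3D U-Net segmenter
# and the two discriminators, with per-iteration pseudo-label refresh, plus
# subject-level three-fold cross-validation.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param phase which unannotated phase to segment: "H" or "E" (the P phase
#'   always provides the annotation).
#' @param variant "full" is the complete model (generator + both
#'   discriminators + pseudo labels); "baseline" trains the plain supervised
#'   3D U-Net on the A-phase block with the P-phase annotation as its label
#'   (no style transfer, no discriminator, no pseudo labels).
#' @param epochs training epochs; defaults 50 (H) / 40 (E).
#' @param learning_rate Adam learning rate; defaults to 0.001 at clinical
#'   scale and 0.01 for the desk preset (matched to its much shorter
#'   optimization schedule).
#' @param batch_size blocks per optimizer step (default 2 clinical,
#'   4 desk scale).
#' @param seed master seed driving weight init, fold assignment and data
#'   order (no augmentation is used anywhere).
#' @param weights a [loss_weights()].
#' @param lambda pseudo-label weights; default per-phase
#'   ([phase_lambda_defaults()]).
#' @param desk_scale use the reduced preset (blocks 32 x 64 x 64, base width
#'   2) that keeps the full pipeline tractable on one CPU; clinical scale is
#'   blocks 32 x 128 x 128 with base width 32.
#' @param base_width,block_shape override the preset.
#' @param warmup_epochs epochs during which the Dice target is True^V itself
#'   instead of the pseudo label (default 0: pseudo labels from epoch 1).
#' @param val_fraction fraction of the training fold held out for model
#'   selection by best validation DSC (against True^V, the only label
#'   available at training time).
#' @param freeze_discriminators skip discriminator updates (diagnostics).
#' @return a `train_config` list.
#' @export
train_config <- function(phase = c("H", "E"),
                         variant = c("full", "baseline"),
                         epochs = NULL,
                         learning_rate = NULL,
                         batch_size = NULL,
                         seed = 1L,
                         weights = loss_weights(),
                         lambda = NULL,
                         desk_scale = FALSE,
                         base_width = NULL,
                         block_shape = NULL,
                         warmup_epochs = 0L,
                         val_fraction = 0.1,
                         freeze_discriminators = FALSE) {
  phase <- match.arg(phase)
  variant <- match.arg(variant)
  epochs <- epochs %||% if (phase == "H") 50L else 40L
  # clinical schedules run thousands of Adam steps at 0.001; the desk preset
  # compresses training into tens of steps and scales the step size to match
  learning_rate <- learning_rate %||% if (desk_scale) 0.01 else 0.001
  stopifnot(epochs >= 1, learning_rate > 0)
  base_width <- base_width %||% if (desk_scale) 2L else 32L
  block_shape <- block_shape %||% if (desk_scale) c(32L, 64L, 64L) else c(32L, 128L, 128L)
  batch_size <- batch_size %||% if (desk_scale) 4L else 2L
  lambda <- lambda %||% phase_lambda_defaults(phase)
  structure(list(phase = phase, variant = variant, epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), weights = weights, lambda = lambda,
                 base_width = as.integer(base_width),
                 block_shape = as.integer(block_shape),
                 warmup_epochs = as.integer(warmup_epochs),
                 val_fraction = val_fraction,
                 freeze_discriminators = freeze_discriminators),
            class = "train_config")
}

#' Subject-level k-fold split
#'
#' Splits subject ids (never blocks) into k disjoint folds.
#'
#' @param ids character vector of subject ids.
#' @param k number of folds (default 3).
#' @param seed shuffle seed.
#' @return a `fold_split`: list of `list(train =, test =)` per fold.
#' @export
make_folds <- function(ids, k = 3L, seed = 1L) {
  stopifnot(length(ids) >= k)
  shuffled <- with_seed(seed, sample(ids))
  assign <- rep_len(seq_len(k), length(ids))
  folds <- lapply(seq_len(k), function(f) {
    test <- shuffled[assign == f]
    list(train = setdiff(shuffled, test), test = test)
  })
  structure(folds, class = "fold_split")
}

# --- optimizer --------------------------------------------------------------

adam_step <- function(params, lr, state, scale = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad * scale
    if (is.null(p$m)) { p$m <- 0 * g; p$v <- 0 * g }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  state
}

# --- model bundle -----------------------------------------------------------

#' Initialize all networks for a training configuration
#'
#' Weight draws come from the current RNG stream; seed beforehand (or use
#' [fit()], which seeds from the config).
#'
#' @param config a [train_config()].
#' @return a `models` list: `unet`, and for the full variant `gen`, `d_img`
#'   (D_A on image blocks) and `d_pred` (D_B on foreground-probability maps).
#' @export
init_models <- function(config) {
  w <- config$base_width
  m <- list(unet = unet_init(unet_config(base_width = w)))
  if (config$variant == "full") {
    m$gen <- generator_init(generator_config(base_width = w))
    m$d_img <- discriminator_init(discriminator_config(base_width = w))
    m$d_pred <- discriminator_init(discriminator_config(base_width = w))
  }
  structure(m, class = "models")
}

# Deep-copy all parameter values of a nested network structure.
net_state <- function(x) {
  if (is_ag_tensor(x)) return(x$value)
  if (is.list(x)) return(lapply(x, net_state))
  x
}

net_restore <- function(net, state) {
  if (is_ag_tensor(net)) { net$value <- state; return(invisible(NULL)) }
  if (is.list(net)) for (nm in seq_along(net)) net_restore(net[[nm]], state[[nm]])
  invisible(NULL)
}

# --- data preparation -------------------------------------------------------

#' Build one subject's training item from a phantom case
#'
#' Runs the preprocessing pipeline (bed removal, alignment, block extraction,
#' normalization) and returns the normalized A- and P-phase blocks, the
#' cropped P-phase annotation, and -- available only synthetically -- the
#' A-phase ground-truth block used for evaluation.
#'
#' @param case a `phantom_case`.
#' @param phase "H" or "E".
#' @param block_shape block extents.
#' @return list with `iA`, `iV`, `trueV`, `truthA`, `origin`.
#' @export
phantom_training_item <- function(case, phase, block_shape = c(32L, 64L, 64L)) {
  pp <- preprocess_subject(case$volumes, case$masks$P, block_shape)
  truthA <- crop_with_origin(case$masks[[phase]] * 1, pp$origin, block_shape, fill = 0)
  list(iA = array(pp$blocks[[phase]], dim = block_shape),
       iV = array(pp$blocks$P, dim = block_shape),
       trueV = pp$trueV,
       truthA = array(truthA, dim = block_shape) > 0,
       origin = pp$origin)
}

# --- one optimization step --------------------------------------------------

#' One training iteration over a batch
#'
#' For every item: style-transfer forward passes I^A -> I^{A->V} and
#' I^V -> I^{V->V}; segmentation of all four blocks; pseudo-label
#' construction from the current binarized predictions and True^V; one Adam
#' update of the generator + U-Net on the eight-term objective; then one
#' Adam update of each discriminator on its binary cross-entropy targets
#' (real: I^V, I^{V->V} for D_A and True^V for D_B; fake: I^{A->V} and the
#' predicted foreground maps).
#'
#' @param models an [init_models()] bundle.
#' @param batch list of items from [phantom_training_item()] (fields `iA`,
#'   `iV`, `trueV`).
#' @param config the [train_config()].
#' @param opt optimizer state (create with `new_opt_state()`).
#' @param epoch current epoch (drives the pseudo-label warm-up).
#' @return a `loss_breakdown` averaged over the batch.
#' @export
train_step <- function(models, batch, config, opt, epoch = 1L) {
  if (config$variant == "baseline") return(train_step_baseline(models, batch, config, opt))
  gu_params <- c(flatten_params(models$gen), flatten_params(models$unet))
  da_params <- flatten_params(models$d_img)
  db_params <- flatten_params(models$d_pred)
  n <- length(batch)
  acc <- NULL
  cache <- vector("list", n)
  ag_zero_grad(c(gu_params, da_params, db_params))
  for (i in seq_len(n)) {
    item <- batch[[i]]
    ag_tape_start()
    iAV <- generator_forward(models$gen, item$iA)
    iVV <- generator_forward(models$gen, item$iV)
    pA <- unet_forward(models$unet, item$iA)
    pAV <- unet_forward(models$unet, iAV)
    pV <- unet_forward(models$unet, item$iV)
    pVV <- unet_forward(models$unet, iVV)
    pseu <- if (epoch <= config$warmup_epochs) item$trueV else
      construct_pseudo_label(binarize_prediction(pA), binarize_prediction(pAV),
                             item$trueV, config$lambda)
    sA <- discriminator_forward(models$d_img, iAV)
    sB <- discriminator_forward(models$d_pred, ag_slice_c(pAV, 2L))
    adv <- generator_adversarial_losses(sA, sB)
    bl <- total_loss(
      iden_img = identity_loss_image(ag_tensor(add_channel(item$iV)), iVV),
      iden_pred = identity_loss_pred(pV, pVV),
      g_img = adv$g_img, g_pred = adv$g_pred,
      con = consistency_loss(pA, pAV),
      ce1 = supervised_ce_loss(pV, item$trueV),
      dice = soft_dice_loss(pAV, pseu),
      ce2 = supervised_ce_loss(pAV, item$trueV),
      w = config$weights)
    if (!is.finite(bl$total)) {
      ag_tape_stop()
      stop("non-finite total loss; breakdown: ",
           paste(sprintf("%s=%g", names(bl)[1:8], unlist(bl[1:8])), collapse = " "))
    }
    ag_backward(bl$total_tensor)
    ag_tape_stop()
    cache[[i]] <- list(iAV = ag_val(iAV), iVV = ag_val(iVV),
                       pAV_fg = ag_val(pAV)[, , , 2, drop = FALSE],
                       pA_fg = ag_val(pA)[, , , 2, drop = FALSE])
    acc <- accumulate_breakdown(acc, bl)
  }
  opt$gu <- adam_step(gu_params, config$learning_rate, opt$gu, scale = 1 / n)
  if (!config$freeze_discriminators) {
    ag_zero_grad(c(da_params, db_params))
    for (i in seq_len(n)) {
      item <- batch[[i]]; cc <- cache[[i]]
      ag_tape_start()
      la <- discriminator_loss(
        list(discriminator_forward(models$d_img, item$iV),
             discriminator_forward(models$d_img, cc$iVV)),
        list(discriminator_forward(models$d_img, cc$iAV)))
      ag_backward(la); ag_tape_stop()
      ag_tape_start()
      tv <- array(as.numeric(item$trueV), dim = c(dim(item$trueV), 1L))
      lb <- discriminator_loss(
        list(discriminator_forward(models$d_pred, tv)),
        list(discriminator_forward(models$d_pred, cc$pAV_fg),
             discriminator_forward(models$d_pred, cc$pA_fg)))
      ag_backward(lb); ag_tape_stop()
    }
    opt$da <- adam_step(da_params, config$learning_rate, opt$da, scale = 1 / n)
    opt$db <- adam_step(db_params, config$learning_rate, opt$db, scale = 1 / n)
  }
  finalize_breakdown(acc, n)
}

train_step_baseline <- function(models, batch, config, opt) {
  u_params <- flatten_params(models$unet)
  n <- length(batch)
  acc <- NULL
  ag_zero_grad(u_params)
  w <- config$weights
  for (item in batch) {
    ag_tape_start()
    pA <- unet_forward(models$unet, item$iA)
    ce <- supervised_ce_loss(pA, item$trueV)
    dc <- soft_dice_loss(pA, array(as.numeric(item$trueV), dim = dim(item$trueV)))
    total <- ag_add(ag_mul(ce, unname(w["omega6"])), ag_mul(dc, unname(w["omega7"])))
    if (!is.finite(ag_val(total))) { ag_tape_stop(); stop("non-finite baseline loss") }
    ag_backward(total)
    ag_tape_stop()
    bl <- structure(list(iden_img = 0, iden_pred = 0, g_img = 0, g_pred = 0,
                         con = 0, ce1 = 0, dice = ag_val(dc), ce2 = ag_val(ce),
                         total = ag_val(total)), class = "loss_breakdown")
    acc <- accumulate_breakdown(acc, bl)
  }
  opt$gu <- adam_step(u_params, config$learning_rate, opt$gu, scale = 1 / n)
  finalize_breakdown(acc, n)
}

#' @keywords internal
new_opt_state <- function() {
  e <- function() { s <- new.env(parent = emptyenv()); s$t <- 0L; s }
  list(gu = e(), da = e(), db = e())
}

accumulate_breakdown <- function(acc, bl) {
  nm <- c("iden_img", "iden_pred", "g_img", "g_pred", "con", "ce1", "dice", "ce2", "total")
  v <- unlist(bl[nm])
  if (is.null(acc)) v else acc + v
}

finalize_breakdown <- function(acc, n) {
  structure(as.list(acc / n), class = "loss_breakdown")
}

add_channel <- function(x) {
  x <- array(as.numeric(x), dim = c(dim(x)[1:3], 1L))
  x
}

# --- prediction -------------------------------------------------------------

#' Segment a block with a trained model
#'
#' The deliverable is the prediction on the ORIGINAL A-phase block
#' (`use_transferred = FALSE`); the prediction on the style-transferred block
#' is available for inspection.
#'
#' @param models an [init_models()] bundle or a loaded checkpoint's models.
#' @param block normalized (D,H,W) block.
#' @param use_transferred segment the generator output instead.
#' @return logical (D,H,W) mask.
#' @export
predict_mask <- function(models, block, use_transferred = FALSE) {
  x <- if (use_transferred) {
    stopifnot(!is.null(models$gen))
    ag_val(generator_forward(models$gen, block))
  } else block
  binarize_prediction(ag_val(unet_forward(models$unet, x)))
}

# --- full training ----------------------------------------------------------

#' Train with subject-level cross-validation
#'
#' For each requested fold: hold out `val_fraction` of the training subjects
#' for model selection, run `config$epochs` epochs of [train_step()] over
#' the remaining subjects, and keep the epoch checkpoint with the best
#' validation DSC (prediction on the A block against True^V -- the only
#' annotation available at training time).
#'
#' @param cohort named list of `phantom_case` objects (or prepared items).
#' @param config a [train_config()].
#' @param n_folds number of folds (default 3).
#' @param fold_subset integer vector of folds to actually run (default all).
#' @param verbose print a line per epoch.
#' @return a `pvseg_fit`: per-fold list of `checkpoint` (network states,
#'   config, best epoch, validation DSC), `log` (per-step loss breakdowns),
#'   and `test_ids`.
#' @export
fit <- function(cohort, config, n_folds = 3L, fold_subset = NULL, verbose = FALSE) {
  ids <- names(cohort)
  folds <- make_folds(ids, n_folds, seed = config$seed)
  fold_subset <- fold_subset %||% seq_len(n_folds)
  items <- lapply(cohort, function(case) {
    if (inherits(case, "phantom_case"))
      phantom_training_item(case, config$phase, config$block_shape)
    else case
  })
  results <- lapply(fold_subset, function(f) {
    train_ids <- folds[[f]]$train
    n_val <- max(1L, round(config$val_fraction * length(train_ids)))
    val_ids <- with_seed(config$seed + f, sample(train_ids, n_val))
    core_ids <- setdiff(train_ids, val_ids)
    set.seed(config$seed + 1000L * f)
    models <- init_models(config)
    opt <- new_opt_state()
    log <- list()
    best <- list(dsc = -Inf, state = NULL, epoch = NA_integer_)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(core_ids)
      bs <- config$batch_size
      starts <- seq(1L, length(ord), by = bs)
      for (s in starts) {
        batch <- items[ord[s:min(s + bs - 1L, length(ord))]]
        bl <- train_step(models, batch, config, opt, epoch = ep)
        log[[length(log) + 1L]] <- c(epoch = ep, unlist(bl[1:9]))
      }
      vd <- mean(vapply(val_ids, function(id) {
        dsc(confusion_counts(predict_mask(models, items[[id]]$iA), items[[id]]$trueV))
      }, numeric(1)))
      if (vd > best$dsc) best <- list(dsc = vd, state = net_state(models), epoch = ep)
      if (verbose)
        message(sprintf("fold %d epoch %d: total=%.4f val_dsc=%.4f",
                        f, ep, bl$total, vd))
    }
    list(checkpoint = structure(list(state = best$state, config = config,
                                     epoch = best$epoch, val_dsc = best$dsc),
                                class = "pvseg_checkpoint"),
         log = as.data.frame(do.call(rbind, log)),
         test_ids = folds[[f]]$test)
  })
  structure(list(folds = results, fold_ids = fold_subset, config = config,
                 split = folds), class = "pvseg_fit")
}

#' Rebuild the model bundle from a checkpoint
#' @param checkpoint a `pvseg_checkpoint`.
#' @return an [init_models()] bundle with restored weights.
#' @export
load_models <- function(checkpoint) {
  models <- with_seed(0L, init_models(checkpoint$config))
  net_restore(models, checkpoint$state)
  models
}

#' Save / load a checkpoint
#'
#' The weights go to an RDS file with a JSON sidecar manifest (epoch,
#' validation DSC, phase, seed).
#'
#' @param checkpoint a `pvseg_checkpoint`.
#' @param path output `.rds` path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  manifest <- list(epoch = checkpoint$epoch, val_dsc = checkpoint$val_dsc,
                   phase = checkpoint$config$phase, seed = checkpoint$config$seed,
                   variant = checkpoint$config$variant)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Evaluate a checkpoint on held-out cases
#'
#' Predictions on the original A-phase blocks are scored against the target
#' phase's own ground-truth masks (available synthetically; this is what the
#' clinical protocol implies but cannot observe).
#'
#' @param checkpoint a `pvseg_checkpoint`.
#' @param cohort named list of `phantom_case`s.
#' @param case_ids which cases to evaluate (default all).
#' @return a [evaluate_masks()] report.
#' @export
evaluate_checkpoint <- function(checkpoint, cohort, case_ids = names(cohort)) {
  if (length(case_ids) == 0L) stop("no test cases")
  models <- load_models(checkpoint)
  cfg <- checkpoint$config
  preds <- list(); truths <- list()
  for (id in case_ids) {
    item <- phantom_training_item(cohort[[id]], cfg$phase, cfg$block_shape)
    preds[[id]] <- predict_mask(models, item$iA)
    truths[[id]] <- item$truthA
  }
  evaluate_masks(preds, truths)
}
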