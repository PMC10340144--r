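# ---------------------------------------------------------------------------
# The eight-term composite objective:
#
#   Loss = w1*L_iden_img + w2*L_iden_pred + w3*L_G_img + w4*L_G_pred
#        + w5*L_CON + w6*L_CE1 + w7*L_dice + w8*L_CE2
#
# Every loss accepts plain arrays (returns a numeric scalar) or autodiff
# tensors (returns a scalar tensor for backpropagation).
# ---------------------------------------------------------------------------

#' Loss-term weights
#'
#' Defaults: `w1 = w2 = w7 = w8 = 5`, `w3 = w4 = 0.01`, `w5 = 1`, `w6 = 10`.
#'
#' @param omega1,omega2,omega3,omega4,omega5,omega6,omega7,omega8 nonnegative
#'   scalars weighting, in order: image identity, prediction identity,
#'   generator-adversarial (image), generator-adversarial (prediction),
#'   consistency, supervised CE on the P phase, soft Dice against the pseudo
#'   label, and supervised CE on the transferred block.
#' @return a `loss_weights` numeric vector.
#' @export
loss_weights <- function(omega1 = 5, omega2 = 5, omega3 = 0.01, omega4 = 0.01,
                         omega5 = 1, omega6 = 10, omega7 = 5, omega8 = 5) {
  w <- c(omega1, omega2, omega3, omega4, omega5, omega6, omega7, omega8)
  if (any(w < 0)) stop("loss weights must be nonnegative")
  structure(w, names = paste0("omega", 1:8), class = "loss_weights")
}

unwrap <- function(x, tensorized) if (tensorized) x else x$value

any_tensor <- function(...) any(vapply(list(...), is_ag_tensor, logical(1)))

check_same_shape <- function(a, b, what) {
  da <- dim(ag_val(a)) %||% length(ag_val(a))
  db <- dim(ag_val(b)) %||% length(ag_val(b))
  if (!identical(da, db)) stop(what, ": shape mismatch")
}

#' Image identity loss
#'
#' Penalizes any change the generator makes to a P-phase block: a piecewise
#' (smooth-L1-style) penalty, `d^2` where `|d| < 1` and `|d| - 0.5`
#' otherwise, over voxel differences between the transferred P block and the
#' original.
#'
#' @param iV original P-phase block.
#' @param iVtoV its style-transferred version.
#' @param reduction "mean" per voxel (default, keeps the published weights
#'   usable across block sizes) or "sum" (the raw printed form).
#' @return scalar (tensor if inputs are tensors).
#' @export
identity_loss_image <- function(iV, iVtoV, reduction = c("mean", "sum")) {
  check_same_shape(iV, iVtoV, "identity_loss_image")
  tz <- any_tensor(iV, iVtoV)
  unwrap(ag_smooth_l1(iV, iVtoV, reduction = match.arg(reduction)), tz)
}

#' Prediction identity loss
#'
#' Same piecewise form as [identity_loss_image()], applied over classes and
#' voxels of the probability maps of the P block and its transferred version.
#'
#' @param pV,pVtoV probability maps (D,H,W,C).
#' @inheritParams identity_loss_image
#' @export
identity_loss_pred <- function(pV, pVtoV, reduction = c("mean", "sum")) {
  check_same_shape(pV, pVtoV, "identity_loss_pred")
  tz <- any_tensor(pV, pVtoV)
  unwrap(ag_smooth_l1(pV, pVtoV, reduction = match.arg(reduction)), tz)
}

#' Generator-side adversarial losses
#'
#' `-log D_A(I^{A->V})` and `-log D_B(P^{A->V})`; scores are clamped to
#' `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param dA_score discriminator D_A score of the transferred image.
#' @param dB_score discriminator D_B score of its prediction.
#' @return list with `g_img` and `g_pred`.
#' @export
generator_adversarial_losses <- function(dA_score, dB_score) {
  list(g_img = adversarial_nll(dA_score), g_pred = adversarial_nll(dB_score))
}

adversarial_nll <- function(score) {
  tz <- is_ag_tensor(score)
  unwrap(ag_neg(ag_log(score)), tz)
}

#' Discriminator loss
#'
#' Binary cross-entropy with target 1 for the real inputs and 0 for the fake
#' inputs, averaged over all items.  Scores are clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param scores_real,scores_fake lists (or vectors) of scalar scores in
#'   (0, 1); tensors allowed.
#' @return scalar (tensor if any score is a tensor).
#' @export
discriminator_loss <- function(scores_real, scores_fake) {
  if (!is.list(scores_real)) scores_real <- as.list(scores_real)
  if (!is.list(scores_fake)) scores_fake <- as.list(scores_fake)
  k <- length(scores_real) + length(scores_fake)
  if (k == 0L) stop("discriminator_loss: empty score lists")
  tz <- any(vapply(c(scores_real, scores_fake), is_ag_tensor, logical(1)))
  total <- NULL
  for (s in scores_real) {
    t <- ag_neg(ag_log(s))
    total <- if (is.null(total)) t else ag_add(total, t)
  }
  for (s in scores_fake) {
    t <- ag_neg(ag_log(ag_sub(1, s)))
    total <- if (is.null(total)) t else ag_add(total, t)
  }
  unwrap(ag_div(total, k), tz)
}

#' Consistency loss
#'
#' Per-class mean squared difference over voxels between the predictions on
#' the original A block and on its transferred version, summed over classes.
#'
#' @param pA,pAtoV probability maps (D,H,W,C).
#' @export
consistency_loss <- function(pA, pAtoV) {
  check_same_shape(pA, pAtoV, "consistency_loss")
  tz <- any_tensor(pA, pAtoV)
  C <- dim(ag_val(pA))[4]
  # mean over all C*N entries times C == sum over classes of per-voxel means
  unwrap(ag_mul(ag_mean(ag_square(ag_sub(pA, pAtoV))), C), tz)
}

#' Supervised cross-entropy loss
#'
#' Standard categorical cross-entropy of a probability map against a binary
#' target, averaged over voxels: `-mean_i sum_c t_ic log p_ic`.
#'
#' @param prediction probability map (D,H,W,C), C = 2 (channel 2 =
#'   foreground).
#' @param target binary (D,H,W) mask, or one-hot (D,H,W,C).
#' @export
supervised_ce_loss <- function(prediction, target) {
  tz <- is_ag_tensor(prediction)
  pv <- ag_val(prediction)
  dm <- dim(pv)
  tv <- ag_val(target)
  if (length(dim(tv)) == 3L || is.null(dim(tv))) {
    t1 <- array(as.numeric(tv), dim = dm[1:3])
    onehot <- array(c(1 - t1, t1), dim = dm)
  } else onehot <- array(as.numeric(tv), dim = dm)
  if (!identical(dim(onehot), dm)) stop("supervised_ce_loss: shape mismatch")
  nvox <- prod(dm[1:3])
  unwrap(ag_div(ag_neg(ag_sum(ag_mul(ag_tensor(onehot), ag_log(prediction)))), nvox), tz)
}

#' Soft Dice loss against a pseudo label
#'
#' `sum_c [1 - (2 sum p q + eps) / (sum p^2 + sum q^2 + eps)]` with p the
#' class-c prediction channel and q the class-c pseudo-label channel
#' (foreground channel = the soft-label values, background = 1 - values).
#'
#' @param pAtoV probability map (D,H,W,C), C = 2.
#' @param pseu a [construct_pseudo_label()] soft label, or a numeric
#'   (D,H,W) foreground-confidence map.
#' @param eps smoothing constant (a class empty in both maps contributes 0).
#' @export
soft_dice_loss <- function(pAtoV, pseu, eps = 1e-7) {
  tz <- is_ag_tensor(pAtoV)
  dm <- dim(ag_val(pAtoV))
  qfg <- array(as.numeric(ag_val(pseu)), dim = dm[1:3])
  if (!identical(dim(qfg), dm[1:3])) stop("soft_dice_loss: shape mismatch")
  qs <- list(array(1 - qfg, dim = c(dm[1:3], 1L)), array(qfg, dim = c(dm[1:3], 1L)))
  total <- NULL
  for (cc in 1:2) {
    p <- ag_slice_c(pAtoV, cc)
    q <- ag_tensor(qs[[cc]])
    num <- ag_add(ag_mul(ag_sum(ag_mul(p, q)), 2), eps)
    den <- ag_add(ag_add(ag_sum(ag_square(p)), ag_sum(ag_square(q))), eps)
    term <- ag_sub(1, ag_div(num, den))
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  unwrap(total, tz)
}

#' Weighted total loss
#'
#' @param iden_img,iden_pred,g_img,g_pred,con,ce1,dice,ce2 the eight loss
#'   terms (numeric scalars or tensors).
#' @param w a [loss_weights()].
#' @return a `loss_breakdown` list: the eight term values, the weighted
#'   `total`, and (when inputs are tensors) `total_tensor` for
#'   backpropagation.
#' @export
total_loss <- function(iden_img, iden_pred, g_img, g_pred, con, ce1, dice, ce2,
                       w = loss_weights()) {
  terms <- list(iden_img = iden_img, iden_pred = iden_pred, g_img = g_img,
                g_pred = g_pred, con = con, ce1 = ce1, dice = dice, ce2 = ce2)
  vals <- lapply(terms, ag_val)
  for (nm in names(vals))
    if (!is.finite(vals[[nm]])) stop("non-finite loss term: ", nm)
  tz <- any(vapply(terms, is_ag_tensor, logical(1)))
  total <- NULL
  for (i in seq_along(terms)) {
    t <- ag_mul(terms[[i]], unname(w[i]))
    total <- if (is.null(total)) t else ag_add(total, t)
  }
  out <- c(lapply(vals, as.numeric), list(total = ag_val(total)))
  if (tz) out$total_tensor <- total
  structure(out, class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  nm <- setdiff(names(x), "total_tensor")
  cat(paste(sprintf("%s=%.5g", nm, unlist(x[nm])), collapse = "  "), "\n")
  invisible(x)
}
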