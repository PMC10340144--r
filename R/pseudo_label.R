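# ---------------------------------------------------------------------------
# Confidence-weighted pseudo labels for cross-phase supervision.  With the
# binarized predictions P^A (on the original A-phase block) and P^(A->V) (on
# its style-transferred counterpart), and the P-phase ground truth True^V,
# the pseudo label is
#
#   Pseu^A = l1 * (P^A & P^(A->V)) + l1 * True^V
#            + (l2 - 2*l1) * (P^A & P^(A->V) & True^V)
#
# so voxels in the triple intersection ("correct label area") receive l2,
# voxels in either the prediction intersection or True^V alone ("possible
# label areas") receive l1, and all other voxels 0.
# ---------------------------------------------------------------------------

#' Pseudo-label confidence weights
#'
#' Defaults follow the per-phase settings: `lambda1 = 0.1` for the H phase,
#' `0.7` for the E phase, with `lambda2 = 1` for both.
#'
#' @param lambda1 weight of "possible" label areas, in \[0, 1\].
#' @param lambda2 weight of the "correct" label area, in \[0, 1\],
#'   `lambda2 >= lambda1`.
#' @return a `pseudo_label_weights` list.
#' @export
pseudo_label_weights <- function(lambda1 = 0.1, lambda2 = 1) {
  stopifnot(lambda1 >= 0, lambda1 <= 1, lambda2 >= 0, lambda2 <= 1)
  if (lambda2 < lambda1) stop("lambda2 must be >= lambda1")
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "pseudo_label_weights")
}

#' Per-phase default pseudo-label weights
#' @param phase "H" or "E".
#' @return a [pseudo_label_weights()].
#' @export
phase_lambda_defaults <- function(phase = c("H", "E")) {
  phase <- match.arg(phase)
  if (phase == "H") pseudo_label_weights(0.1, 1) else pseudo_label_weights(0.7, 1)
}

#' Binarize a probability map
#'
#' Foreground where the foreground-class probability strictly exceeds the
#' threshold; at the default 0.5 this is the two-class argmax with ties going
#' to background.
#'
#' @param p probability map: (D,H,W,C) array or tensor with C = 2 (class 2 =
#'   portal vein / foreground).
#' @param threshold scalar in (0, 1).
#' @return logical (D,H,W) mask.
#' @export
binarize_prediction <- function(p, threshold = 0.5) {
  v <- ag_val(p)
  stopifnot(length(dim(v)) == 4L)
  fg <- v[, , , dim(v)[4], drop = TRUE]
  fg > threshold
}

#' Construct the confidence-weighted pseudo label
#'
#' @param pA binarized prediction on the original A-phase block.
#' @param pAtoV binarized prediction on the style-transferred block.
#' @param trueV P-phase ground-truth mask.
#' @param w a [pseudo_label_weights()].
#' @return a `soft_label`: numeric array with every voxel in
#'   `{0, lambda1, lambda2}`, with a `region` attribute coding the
#'   provenance (0 none, 1 prediction intersection only, 2 True^V only,
#'   3 triple intersection).
#' @export
construct_pseudo_label <- function(pA, pAtoV, trueV, w = pseudo_label_weights()) {
  shp <- dim(trueV) %||% length(trueV)
  if (length(pA) != length(trueV) || length(pAtoV) != length(trueV) ||
      !identical(dim(pA), dim(trueV)) || !identical(dim(pAtoV), dim(trueV)))
    stop("pseudo-label inputs must share one shape")
  a <- array(as.logical(pA), dim = shp)
  b <- array(as.logical(pAtoV), dim = shp)
  t <- array(as.logical(trueV), dim = shp)
  inter <- a & b
  values <- w$lambda1 * inter + w$lambda1 * t + (w$lambda2 - 2 * w$lambda1) * (inter & t)
  region <- (inter & !t) * 1L + (!inter & t) * 2L + (inter & t) * 3L
  structure(values, region = region, lambda = unlist(w[c("lambda1", "lambda2")]),
            class = c("soft_label", "array"))
}

#' Write a soft label to NIfTI for inspection
#' @param label a `soft_label`.
#' @param path output file.
#' @export
write_soft_label <- function(label, path) {
  RNifti::writeNifti(array(label, dim = dim(label)), path)
  invisible(path)
}
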