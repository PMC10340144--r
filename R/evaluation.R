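# ---------------------------------------------------------------------------
# Voxel-level confusion-count metrics and cohort reports.
#
# Two "Jaccard" variants are reported side by side on purpose:
# `jaccard_printed` is (TN+TP)/(TN+TP+FP+FN) -- algebraically voxel accuracy,
# which rewards all-background predictions on sparse targets -- while
# `jaccard_standard` is the usual intersection-over-union TP/(TP+FP+FN).
# ---------------------------------------------------------------------------

#' Voxel confusion counts for the foreground class
#'
#' @param pred,truth binary/logical arrays of one shape.
#' @return a `confusion_counts` list (tp, tn, fp, fn).
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth) || !identical(dim(pred), dim(truth)))
    stop("confusion_counts: shape mismatch")
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

as_counts <- function(x) {
  if (inherits(x, "confusion_counts")) return(x)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(x)))
  structure(as.list(x[c("tp", "tn", "fp", "fn")]), class = "confusion_counts")
}

#' Dice similarity coefficient
#'
#' `2TP / (2TP + FP + FN)`; defined as 1 when TP, FP and FN are all zero
#' (empty prediction of an empty target).
#'
#' @param counts a [confusion_counts()] (or list with tp/tn/fp/fn).
#' @return scalar in \[0, 1\].
#' @export
dsc <- function(counts) {
  c <- as_counts(counts)
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) 1 else 2 * c$tp / den
}

#' Jaccard as printed (voxel accuracy)
#'
#' `(TN + TP) / (TN + TP + FP + FN)`.  This is voxel accuracy, not the
#' standard Jaccard index; see [jaccard_standard()].
#'
#' @inheritParams dsc
#' @export
jaccard_printed <- function(counts) {
  c <- as_counts(counts)
  (c$tn + c$tp) / (c$tn + c$tp + c$fp + c$fn)
}

#' Standard Jaccard index (intersection over union)
#'
#' `TP / (TP + FP + FN)`; 1 when all three are zero.  Relates to Dice by
#' `J = D / (2 - D)`.
#'
#' @inheritParams dsc
#' @export
jaccard_standard <- function(counts) {
  c <- as_counts(counts)
  den <- c$tp + c$fp + c$fn
  if (den == 0) 1 else c$tp / den
}

#' Per-case segmentation metrics
#'
#' @param preds,truths named lists of binary masks (one entry per case).
#' @return a `metrics_report` data.frame with one row per case (dsc,
#'   jaccard_printed, jaccard_standard) and a `summary` attribute holding
#'   mean and sd of each metric.
#' @export
evaluate_masks <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) > 0L)
  ids <- names(preds) %||% sprintf("case%02d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    cc <- confusion_counts(preds[[i]], truths[[i]])
    data.frame(case = ids[i], dsc = dsc(cc),
               jaccard_printed = jaccard_printed(cc),
               jaccard_standard = jaccard_standard(cc),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  met <- c("dsc", "jaccard_printed", "jaccard_standard")
  attr(rep, "summary") <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(rep[[m]]), numeric(1)),
    sd = vapply(met, function(m) stats::sd(rep[[m]]), numeric(1)),
    row.names = NULL)
  class(rep) <- c("metrics_report", "data.frame")
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("--\n")
  print(attr(x, "summary"), row.names = FALSE, digits = 4)
  invisible(x)
}
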