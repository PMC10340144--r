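# ---------------------------------------------------------------------------
# Volumetric preprocessing: CT-bed removal, cross-phase axial alignment,
# annotation-centered block extraction and intensity normalization.  Axes are
# (depth/axial, height, width); voxel indices reported to the user are
# 0-based.
# ---------------------------------------------------------------------------

#' Default HU clipping window for normalization
#'
#' Soft-tissue/contrast window used before min-max scaling; its lower bound
#' also serves as the background fill value for removed bed voxels and block
#' padding.
#' @export
hu_window <- function() c(-200, 400)

#' Remove the CT bed from a volume
#'
#' Thresholds the volume at `threshold_hu`, keeps the largest 3D connected
#' component (the body), and fills everything else with `fill`.
#'
#' @param volume 3D HU array (depth, height, width).
#' @param threshold_hu binarization threshold (default -300 HU).
#' @param fill replacement intensity for non-body voxels (default the lower
#'   bound of [hu_window()]).
#' @return list with `volume` (bed-removed array) and `body_mask` (logical
#'   array, one connected component, with per-axial-slice foreground flags as
#'   attribute `slice_flag`).
#' @export
remove_ct_bed <- function(volume, threshold_hu = -300, fill = hu_window()[1]) {
  stopifnot(length(dim(volume)) == 3L, length(volume) > 0L)
  fg <- volume > threshold_hu
  if (!any(fg)) stop("empty foreground after thresholding at ", threshold_hu, " HU")
  lab <- cpp_label3d(fg, dim(volume))
  sizes <- tabulate(lab)
  keep <- which.max(sizes)
  body <- array(lab == keep, dim = dim(volume))
  out <- volume
  out[!body] <- fill
  attr(body, "slice_flag") <- apply(body, 1L, any)
  list(volume = out, body_mask = body)
}

#' Align three phase volumes axially
#'
#' The phases of one subject may have different axial slice counts.  The
#' contiguous axial window (of length equal to the shortest phase) whose
#' three-phase body-mask intersection has the largest voxel count is selected
#' by exhaustive search over per-phase axial offsets; ties are broken by the
#' smallest offsets.  This is a 1-D slice-location alignment, not a spatial
#' registration: the residual in-plane vessel shift is handled downstream by
#' the pseudo labels.
#'
#' @param volumes list of three 3D arrays (same in-plane extents).
#' @param masks list of three body masks (from [remove_ct_bed()]).
#' @return list of three axially cropped volumes of equal slice count, with
#'   attributes `offsets` (0-based per-phase start offsets) and
#'   `intersection` (voxel count of the best window).
#' @export
align_phases <- function(volumes, masks) {
  stopifnot(length(volumes) == 3L, length(masks) == 3L)
  ns <- vapply(volumes, function(v) dim(v)[1], integer(1))
  L <- min(ns)
  offs <- lapply(ns, function(n) 0:(n - L))
  best <- list(count = -1, o = NULL)
  for (o1 in offs[[1]]) for (o2 in offs[[2]]) for (o3 in offs[[3]]) {
    cnt <- sum(masks[[1]][o1 + seq_len(L), , ] &
               masks[[2]][o2 + seq_len(L), , ] &
               masks[[3]][o3 + seq_len(L), , ])
    if (cnt > best$count) best <- list(count = cnt, o = c(o1, o2, o3))
  }
  if (best$count <= 0) stop("no overlapping axial window across the three phases")
  out <- lapply(1:3, function(i) {
    v <- volumes[[i]][best$o[i] + seq_len(L), , , drop = FALSE]
    v
  })
  names(out) <- names(volumes)
  attr(out, "offsets") <- best$o
  attr(out, "intersection") <- best$count
  out
}

#' Extract an annotation-centered block
#'
#' Crops a block of `block_shape` centered on the voxel centroid of the
#' P-phase portal-vein annotation; the same origin is meant to be reused for
#' all phases of a subject.  Crops exceeding the volume bounds are padded
#' with `fill`.
#'
#' @param volume 3D array (aligned).
#' @param annotation binary/logical 3D array, nonempty.
#' @param block_shape integer (depth, height, width); default 32 x 128 x 128.
#' @param fill padding intensity.
#' @return a `pv_block`: array of exactly `block_shape` with attributes
#'   `origin` (0-based voxel offset into the source) and `normalized`.
#' @export
extract_block <- function(volume, annotation, block_shape = c(32L, 128L, 128L),
                          fill = hu_window()[1]) {
  stopifnot(all(dim(volume) == dim(annotation)))
  idx <- which(annotation != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty annotation: cannot locate a portal-vein block")
  block_shape <- as.integer(block_shape)
  centroid0 <- round(colMeans(idx)) - 1L            # 0-based
  origin0 <- as.integer(centroid0) - block_shape %/% 2L
  crop_with_origin(volume, origin0, block_shape, fill)
}

#' Crop a block at a fixed 0-based origin (padding out-of-range voxels)
#'
#' @inheritParams extract_block
#' @param origin0 0-based voxel offset of the block corner.
#' @return a `pv_block` array.
#' @export
crop_with_origin <- function(volume, origin0, block_shape, fill = hu_window()[1]) {
  block_shape <- as.integer(block_shape)
  out <- array(fill, dim = block_shape)
  src_lo <- pmax(origin0 + 1L, 1L)
  src_hi <- pmin(origin0 + block_shape, dim(volume))
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - origin0
    dst_hi <- src_hi - origin0
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      volume[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  structure(out, origin = as.integer(origin0), normalized = FALSE,
            class = c("pv_block", "array"))
}

#' Normalize a block to [0, 1]
#'
#' Clips intensities to the HU window and min-max scales the block to
#' \[0, 1\].  Constant blocks map to all zeros.  Idempotent: normalizing a
#' normalized block returns it unchanged.
#'
#' @param block a `pv_block` or plain 3D array (HU).
#' @param clip HU clipping window.
#' @return the normalized block (attribute `normalized = TRUE`).
#' @export
normalize_block <- function(block, clip = hu_window()) {
  if (isTRUE(attr(block, "normalized"))) return(block)
  x <- pmin(pmax(block, clip[1]), clip[2])
  rng <- range(x)
  y <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else array(0, dim = dim(block))
  structure(array(y, dim = dim(block)), origin = attr(block, "origin"),
            normalized = TRUE, class = c("pv_block", "array"))
}

#' Preprocess one subject's three phases into training blocks
#'
#' Full pipeline in order: bed removal, axial alignment, annotation-centered
#' block extraction (same origin for every phase), normalization.
#'
#' @param volumes named list (`H`, `P`, `E`) of 3D HU arrays.
#' @param annotation P-phase portal-vein mask (on the unaligned P volume).
#' @param block_shape block extents.
#' @param skip_bed_removal set TRUE when volumes are already body-only.
#' @return list with normalized blocks per phase, the cropped annotation
#'   block `trueV`, and the shared 0-based `origin`.
#' @export
preprocess_subject <- function(volumes, annotation,
                               block_shape = c(32L, 128L, 128L),
                               skip_bed_removal = FALSE) {
  stopifnot(all(c("H", "P", "E") %in% names(volumes)))
  if (skip_bed_removal) {
    cleaned <- volumes[c("H", "P", "E")]
    bmasks <- lapply(cleaned, function(v) v > -300)
  } else {
    br <- lapply(volumes[c("H", "P", "E")], remove_ct_bed)
    cleaned <- lapply(br, `[[`, "volume")
    bmasks <- lapply(br, `[[`, "body_mask")
  }
  aligned <- align_phases(cleaned, bmasks)
  o <- attr(aligned, "offsets")
  L <- dim(aligned[[1]])[1]
  ann <- annotation[o[2] + seq_len(L), , , drop = FALSE]
  pb <- extract_block(aligned$P, ann, block_shape)
  origin0 <- attr(pb, "origin")
  blocks <- lapply(aligned, function(v) {
    normalize_block(crop_with_origin(v, origin0, block_shape))
  })
  trueV <- crop_with_origin(ann * 1, origin0, block_shape, fill = 0)
  list(blocks = blocks, trueV = array(trueV, dim = block_shape),
       origin = origin0, axial_offsets = o)
}

#' Read a NIfTI volume as a plain array
#' @param path file path.
#' @return 3D numeric array.
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}
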