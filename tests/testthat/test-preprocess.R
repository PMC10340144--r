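test_that("bed removal keeps exactly the largest connected component", {
  # two components: a 1000-voxel slab and a 10-voxel blob, plus a bed below
  # threshold
  vol <- array(-1024, dim = c(10, 20, 20))
  vol[1:10, 2:11, 2:11] <- 50          # 1000 voxels
  vol[1:10, 15, 15] <- 50              # 10 voxels, disconnected
  vol[, 19:20, ] <- -1000              # bed slab, below -300
  out <- remove_ct_bed(vol)
  expect_equal(sum(out$body_mask), 1000)
  expect_true(all(out$body_mask[, 2:11, 2:11][vol[, 2:11, 2:11] > -300]))
  expect_false(any(out$body_mask[, 15, 15]))
  expect_false(any(out$body_mask[, 19:20, ]))
  expect_true(all(out$volume[!out$body_mask] == hu_window()[1]))
})

test_that("bed removal spans the whole volume when all voxels are above threshold", {
  vol <- array(100, dim = c(4, 4, 4))
  out <- remove_ct_bed(vol)
  expect_true(all(out$body_mask))
})

test_that("bed removal errors on an empty foreground", {
  expect_error(remove_ct_bed(array(-1024, dim = c(4, 4, 4))), "empty foreground")
})

test_that("phantom bed voxels are excluded from the body mask", {
  case <- generate_phantom(phantom_params(seed = 4))
  out <- remove_ct_bed(case$volumes$P)
  expect_false(any(out$body_mask[case$bed_mask]))
  expect_true(all(out$body_mask[case$masks$P]))
})

test_that("alignment recovers a planted axial shift and matches brute force", {
  set.seed(31)
  base <- array(FALSE, dim = c(16, 8, 8))
  for (d in 3:14) base[d, 3:6, 3:6] <- TRUE   # body occupying slices 3..14
  vol_of <- function(m) array(ifelse(m, 100, -1024), dim = dim(m))
  # phase 2 shifted by +2 slices, padded to 18 slices
  shifted <- array(FALSE, dim = c(18, 8, 8))
  shifted[(3:14) + 2, 3:6, 3:6] <- TRUE
  vols <- list(vol_of(base), vol_of(shifted), vol_of(base))
  masks <- list(base, shifted, base)
  out <- align_phases(vols, masks)
  expect_equal(attr(out, "offsets"), c(0, 2, 0))
  expect_true(all(vapply(out, function(v) dim(v)[1], numeric(1)) == 16))
  # independent brute force over all offset combinations
  L <- 16
  best <- -1; best_o <- NULL
  for (o2 in 0:2) {
    cnt <- sum(base & shifted[o2 + seq_len(L), , ] & base)
    if (cnt > best) { best <- cnt; best_o <- o2 }
  }
  expect_equal(attr(out, "offsets")[2], best_o)
  expect_equal(attr(out, "intersection"), best)
})

test_that("alignment of identical volumes is the identity crop", {
  case <- generate_phantom(phantom_params(grid_shape = c(8, 16, 16), seed = 6))
  m <- lapply(1:3, function(i) case$body_mask)
  v <- lapply(1:3, function(i) case$volumes$P)
  out <- align_phases(v, m)
  expect_equal(attr(out, "offsets"), c(0, 0, 0))
  expect_identical(array(out[[1]], dim = dim(case$volumes$P)), case$volumes$P)
})

test_that("alignment errors when body masks are disjoint", {
  a <- array(FALSE, dim = c(4, 4, 4)); a[, 1, ] <- TRUE
  b <- array(FALSE, dim = c(4, 4, 4)); b[, 3, ] <- TRUE
  v <- array(0, dim = c(4, 4, 4))
  expect_error(align_phases(list(v, v, v), list(a, b, a)), "no overlapping")
})

test_that("block extraction centers on the annotation centroid", {
  vol <- array(seq_len(8^3), dim = c(8, 8, 8))
  ann <- array(0, dim = c(8, 8, 8))
  ann[5, 5, 5] <- 1                       # 0-based voxel (4,4,4)
  blk <- extract_block(vol, ann, block_shape = c(4, 4, 4))
  expect_equal(attr(blk, "origin"), c(2L, 2L, 2L))
  expect_equal(dim(blk), c(4L, 4L, 4L))
  expect_equal(blk[1, 1, 1], vol[3, 3, 3])
})

test_that("corner blocks are padded with the fill value and keep their shape", {
  vol <- array(100, dim = c(8, 8, 8))
  ann <- array(0, dim = c(8, 8, 8)); ann[1, 1, 1] <- 1
  blk <- extract_block(vol, ann, block_shape = c(6, 6, 6))
  expect_equal(dim(blk), c(6L, 6L, 6L))
  expect_equal(attr(blk, "origin"), c(-3L, -3L, -3L))
  expect_equal(blk[1, 1, 1], hu_window()[1])    # padded corner
  expect_equal(blk[4, 4, 4], 100)               # voxel (0,0,0) of the source
})

test_that("block extraction rejects an empty annotation", {
  vol <- array(0, dim = c(8, 8, 8))
  expect_error(extract_block(vol, array(0, dim = c(8, 8, 8))), "empty annotation")
})

test_that("normalization maps the clipping window to [0,1] and is idempotent", {
  blk <- structure(array(seq(-100, 300, length.out = 64), dim = c(4, 4, 4)),
                   normalized = FALSE, class = c("pv_block", "array"))
  nb <- normalize_block(blk)
  expect_equal(min(nb), 0)
  expect_equal(max(nb), 1)
  expect_identical(array(normalize_block(nb), dim = dim(nb)), array(nb, dim = dim(nb)))
  # constant block maps to zeros
  cb <- normalize_block(array(77, dim = c(4, 4, 4)))
  expect_true(all(cb == 0))
  # clipping: values beyond the window saturate before scaling
  wide <- normalize_block(array(c(-500, 0, 500, rep(0, 61)), dim = c(4, 4, 4)))
  expect_equal(max(wide), 1)
  expect_equal(min(wide), 0)
})

test_that("the subject pipeline reuses one origin across phases", {
  case <- generate_phantom(phantom_params(seed = 12))
  pp <- preprocess_subject(case$volumes, case$masks$P, block_shape = c(16, 32, 32))
  expect_equal(dim(pp$blocks$H), c(16L, 32L, 32L))
  expect_equal(attr(pp$blocks$H, "origin"), pp$origin)
  expect_equal(attr(pp$blocks$E, "origin"), pp$origin)
  expect_true(all(pp$blocks$P >= 0 & pp$blocks$P <= 1))
  expect_gt(sum(pp$trueV), 0)
})
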