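# ---------------------------------------------------------------------------
# Synthetic multiphase CTA phantom: tubular vessel trees embedded in a body
# ellipsoid over a CT-bed slab, with phase-dependent vessel contrast and a
# small inter-phase displacement/warp of the vessel.  Axes are ordered
# (depth/axial, height, width).
# ---------------------------------------------------------------------------

#' Phantom generation parameters
#'
#' Defines a three-phase (H, P, E) synthetic volume of one subject.  Vessel
#' contrast against the body background must be ordered P > E > H, emulating
#' the contrast-media kinetics of hepatic CTA: lowest in the arterial
#' (H) phase, highest in the portal-venous (P) phase, intermediate in the
#' equilibrium (E) phase.
#'
#' @param grid_shape integer (depth, height, width) in voxels, each >= 8.
#' @param n_branches number of vessel tubes (>= 1).
#' @param vessel_radius_range numeric length-2, tube radius range in voxels
#'   (>= 1).
#' @param phase_contrast named list `H`/`P`/`E`, each `c(vessel=, background=,
#'   noise=)` in HU.
#' @param interphase_shift maximum voxel translation of the vessel between the
#'   P phase and the H/E phases.
#' @param interphase_warp_amplitude amplitude (voxels) of a smooth sinusoidal
#'   warp of the vessel centerline in the H/E phases.
#' @param seed integer RNG seed.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(32L, 64L, 64L),
                           n_branches = 3L,
                           vessel_radius_range = c(1.5, 3),
                           phase_contrast = list(
                             H = c(vessel = 100, background = 60, noise = 15),
                             P = c(vessel = 230, background = 60, noise = 15),
                             E = c(vessel = 150, background = 60, noise = 15)),
                           interphase_shift = 2,
                           interphase_warp_amplitude = 1,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three extents, each >= 8")
  if (n_branches < 1L) stop("n_branches must be >= 1")
  if (any(vessel_radius_range < 1)) stop("vessel radii must be >= 1 voxel")
  for (ph in c("H", "P", "E")) {
    pc <- phase_contrast[[ph]]
    if (is.null(pc) || !all(c("vessel", "background", "noise") %in% names(pc)))
      stop("phase_contrast$", ph, " must provide vessel, background, noise")
    if (pc["noise"] < 0) stop("noise sd must be >= 0")
  }
  sep <- vapply(phase_contrast, function(pc) unname(pc["vessel"] - pc["background"]),
                numeric(1))
  if (!(sep["P"] > sep["E"] && sep["E"] > sep["H"]))
    stop("vessel-background separation must be ordered P > E > H")
  if (interphase_shift >= min(grid_shape))
    stop("interphase_shift larger than grid")
  if (interphase_shift < 0 || interphase_warp_amplitude < 0)
    stop("shift and warp amplitude must be >= 0")
  structure(list(grid_shape = grid_shape, n_branches = as.integer(n_branches),
                 vessel_radius_range = vessel_radius_range,
                 phase_contrast = phase_contrast,
                 interphase_shift = interphase_shift,
                 interphase_warp_amplitude = interphase_warp_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Rasterize vessel centerlines (per-axial-slice disk model) into a mask.
rasterize_tubes <- function(branches, grid) {
  D <- grid[1]; H <- grid[2]; W <- grid[3]
  mask <- array(FALSE, dim = grid)
  hg <- matrix(seq_len(H), H, W)
  wg <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (br in branches) {
    r2 <- br$radius^2
    for (k in seq_along(br$d)) {
      d <- br$d[k]
      if (d < 1 || d > D) next
      disk <- (hg - br$h[k])^2 + (wg - br$w[k])^2 <= r2
      mask[d, , ][disk] <- TRUE
    }
  }
  mask
}

#' Generate one synthetic multiphase phantom
#'
#' Produces three co-subject volumes (H, P, E) in HU with per-phase vessel
#' masks.  The P-phase mask plays the role of the annotation ground truth;
#' the H/E masks are translated/warped copies of the same vessel tree,
#' emulating inter-phase vessel shift.  A flat bed slab below the body is
#' rendered at -1000 HU so that bed removal can be exercised.
#'
#' @param params a [phantom_params()].
#' @return a `phantom_case` with elements `volumes` (phase -> HU array),
#'   `masks` (phase -> logical array), `body_mask`, and `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, {
    grid <- params$grid_shape
    D <- grid[1]; H <- grid[2]; W <- grid[3]

    # body ellipsoid (in-plane), constant along depth
    ch <- H / 2; cw <- W / 2
    ah <- 0.34 * H; aw <- 0.42 * W
    hg <- matrix(seq_len(H), H, W)
    wg <- matrix(seq_len(W), H, W, byrow = TRUE)
    body2d <- ((hg - ch) / ah)^2 + ((wg - cw) / aw)^2 <= 1
    body_mask <- array(rep(body2d, each = D), dim = grid)

    # bed: flat slab under the body (larger height index = lower on the table)
    bed2d <- matrix(FALSE, H, W)
    bed2d[(H - 2L):H, ] <- TRUE
    bed2d <- bed2d & !body2d
    bed_mask <- array(rep(bed2d, each = D), dim = grid)

    # vessel centerlines: main branch runs axially with a smooth random walk;
    # side branches leave the main branch with a constant drift
    margin <- max(params$vessel_radius_range) + 2
    clamp_in <- function(h, w) {
      # keep centerline inside the body ellipse with a safety margin
      f <- sqrt(((h - ch) / (ah - margin))^2 + ((w - cw) / (aw - margin))^2)
      bad <- f > 1
      h[bad] <- ch + (h[bad] - ch) / f[bad]
      w[bad] <- cw + (w[bad] - cw) / f[bad]
      list(h = h, w = w)
    }
    branches <- vector("list", params$n_branches)
    h0 <- ch + stats::runif(1, -0.1, 0.1) * H
    w0 <- cw + stats::runif(1, -0.1, 0.1) * W
    hs <- h0 + cumsum(stats::rnorm(D, 0, 0.4))
    ws <- w0 + cumsum(stats::rnorm(D, 0, 0.4))
    cc <- clamp_in(hs, ws)
    branches[[1]] <- list(d = seq_len(D), h = cc$h, w = cc$w,
                          radius = stats::runif(1, params$vessel_radius_range[1],
                                                params$vessel_radius_range[2]))
    if (params$n_branches > 1L) {
      for (b in 2:params$n_branches) {
        i0 <- sample(seq_len(max(D - 4L, 1L)), 1L)
        len <- D - i0 + 1L
        drift_h <- stats::runif(1, -0.9, 0.9)
        drift_w <- stats::runif(1, -0.9, 0.9)
        hb <- branches[[1]]$h[i0] + cumsum(rep(drift_h, len) + stats::rnorm(len, 0, 0.3))
        wb <- branches[[1]]$w[i0] + cumsum(rep(drift_w, len) + stats::rnorm(len, 0, 0.3))
        cc <- clamp_in(hb, wb)
        branches[[b]] <- list(d = i0:D, h = cc$h, w = cc$w,
                              radius = stats::runif(1, params$vessel_radius_range[1],
                                                    params$vessel_radius_range[2]))
      }
    }

    # per-phase displaced/warped copies of the centerlines (P = reference)
    shift_branches <- function(branches, shift, amp) {
      if (shift == 0 && amp == 0) return(branches)
      sh <- stats::runif(3, -shift, shift)        # (d, h, w) translation
      phi <- stats::runif(2, 0, 2 * pi)
      lapply(branches, function(br) {
        t <- br$d / max(br$d)
        br$h <- br$h + sh[2] + amp * sin(2 * pi * t + phi[1])
        br$w <- br$w + sh[3] + amp * sin(2 * pi * t + phi[2])
        br$d <- br$d + round(sh[1])
        br
      })
    }
    masks <- list(
      H = rasterize_tubes(shift_branches(branches, params$interphase_shift,
                                         params$interphase_warp_amplitude), grid),
      P = rasterize_tubes(branches, grid),
      E = rasterize_tubes(shift_branches(branches, params$interphase_shift,
                                         params$interphase_warp_amplitude), grid)
    )
    masks <- lapply(masks, function(m) m & body_mask)

    volumes <- lapply(c(H = "H", P = "P", E = "E"), function(ph) {
      pc <- params$phase_contrast[[ph]]
      vol <- array(-1024, dim = grid)
      nb <- sum(body_mask)
      vol[body_mask] <- stats::rnorm(nb, pc["background"], pc["noise"])
      vol[bed_mask] <- -1000
      nv <- sum(masks[[ph]])
      if (nv > 0) vol[masks[[ph]]] <- stats::rnorm(nv, pc["vessel"], pc["noise"])
      vol
    })

    structure(list(volumes = volumes, masks = masks, body_mask = body_mask,
                   bed_mask = bed_mask, params = params),
              class = "phantom_case")
  })
}

#' Generate a cohort of phantoms
#'
#' Per-case seeds are drawn reproducibly from the master seed, so cohorts are
#' deterministic and cases mutually independent.
#'
#' @param n_cases number of subjects (>= 1).
#' @param params shared [phantom_params()] (the per-case `seed` is replaced).
#' @param seed master seed.
#' @return a named list of `phantom_case` objects (`case01`, `case02`, ...).
#' @export
generate_cohort <- function(n_cases, params = phantom_params(), seed = params$seed) {
  stopifnot(n_cases >= 1)
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_cases))
  out <- lapply(seq_len(n_cases), function(i) {
    p <- params
    p$seed <- case_seeds[i]
    generate_phantom(p)
  })
  names(out) <- sprintf("case%02d", seq_len(n_cases))
  out
}

#' Mean vessel-to-background separation of a phantom phase
#'
#' Mean intensity inside the phase's vessel mask minus mean intensity of the
#' non-vessel body interior.
#'
#' @param case a `phantom_case`.
#' @param phase one of "H", "P", "E".
#' @return a scalar in HU.
#' @export
phase_separation <- function(case, phase) {
  m <- case$masks[[phase]]
  v <- case$volumes[[phase]]
  mean(v[m]) - mean(v[case$body_mask & !m])
}

#' Write a cohort to disk as NIfTI plus a JSON manifest
#'
#' @param cohort a list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(names(cohort), function(id) {
    case <- cohort[[id]]
    paths <- list()
    for (ph in c("H", "P", "E")) {
      vp <- file.path(dir, paste0(id, "_", ph, ".nii.gz"))
      mp <- file.path(dir, paste0(id, "_", ph, "_mask.nii.gz"))
      RNifti::writeNifti(case$volumes[[ph]], vp)
      RNifti::writeNifti(case$masks[[ph]] * 1L, mp)
      paths[[ph]] <- list(volume = basename(vp), mask = basename(mp))
    }
    paths
  })
  names(manifest) <- names(cohort)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' @export
print.phantom_case <- function(x, ...) {
  g <- x$params$grid_shape
  cat("multiphase phantom ", paste(g, collapse = "x"),
      ", vessel voxels (H/P/E): ",
      paste(vapply(x$masks, sum, numeric(1)), collapse = "/"), "\n", sep = "")
  invisible(x)
}
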