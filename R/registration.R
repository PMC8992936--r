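#' Configuration for rigid auto-registration
#'
#' Mirrors the clinical bone-match protocol: similarity is mutual
#' information computed over reference voxels inside a bone-threshold
#' window (default 200-1700 HU) and an optional volume of interest;
#' optimization is a deterministic downhill simplex (Nelder-Mead).
#'
#' @param hu_lo,hu_hi bone HU window (defaults 200 and 1700)
#' @param voi optional axis-aligned box `c(x0, y0, z0, x1, y1, z1)` in mm;
#'   `NULL` uses the whole image
#' @param n_bins joint-histogram bins per channel for mutual information
#' @param max_iter simplex iteration budget per start
#' @param xtol,ftol convergence tolerances (ftol drives the simplex
#'   relative-tolerance stop; xtol is retained for reporting)
#' @param multires_levels 1 (single resolution) or 2 (x2-downsampled
#'   initial level to widen the capture range)
#' @param mask_dilate_vox voxels of dilation applied to the bone mask when
#'   evaluating similarity. The bone/soft-tissue boundary carries the
#'   intensity information the joint histogram needs (inside homogeneous
#'   bone the reference is constant and mutual information is blind), so
#'   the similarity region is the thresholded mask plus this capture shell
#' @param init initial [six_dof()] estimate
#' @return object of class `registration_config`
#' @export
registration_config <- function(hu_lo = 200, hu_hi = 1700, voi = NULL,
                                n_bins = 64L, max_iter = 400L,
                                xtol = 1e-3, ftol = 1e-7,
                                multires_levels = 1L,
                                mask_dilate_vox = 2L, init = six_dof()) {
  if (!(hu_lo < hu_hi)) stop("`hu_lo` must be < `hu_hi`")
  if (n_bins < 8L) stop("`n_bins` must be >= 8")
  if (xtol <= 0 || ftol <= 0) stop("tolerances must be > 0")
  if (!is.null(voi)) {
    voi <- as.numeric(voi)
    if (length(voi) != 6L || any(voi[4:6] < voi[1:3]))
      stop("`voi` must be c(x0, y0, z0, x1, y1, z1) with upper >= lower")
  }
  if (!multires_levels %in% c(1L, 2L))
    stop("`multires_levels` must be 1 or 2")
  structure(list(hu_lo = hu_lo, hu_hi = hu_hi, voi = voi,
                 n_bins = as.integer(n_bins), max_iter = as.integer(max_iter),
                 xtol = xtol, ftol = ftol,
                 multires_levels = as.integer(multires_levels),
                 mask_dilate_vox = as.integer(mask_dilate_vox),
                 init = .as_six_dof(init)),
            class = "registration_config")
}

#' Bone-threshold mask of a reference volume
#'
#' Marks voxels whose HU lies within the configured bone window and whose
#' centre falls inside the volume of interest. Registration similarity is
#' evaluated over these voxels only, matching clinical bony-anatomy
#' matching.
#'
#' @param vol a [volume_image()] in HU
#' @param cfg a [registration_config()]
#' @return logical array of the volume's dimensions
#' @export
bone_mask <- function(vol, cfg = registration_config()) {
  m <- vol$data >= cfg$hu_lo & vol$data <= cfg$hu_hi
  if (!is.null(cfg$voi)) {
    pts <- voxel_coordinates(vol, which = which(m))
    inside <- pts[, 1] >= cfg$voi[1] & pts[, 1] <= cfg$voi[4] &
      pts[, 2] >= cfg$voi[2] & pts[, 2] <= cfg$voi[5] &
      pts[, 3] >= cfg$voi[3] & pts[, 3] <= cfg$voi[6]
    keep <- which(m)[inside]
    m[] <- FALSE
    m[keep] <- TRUE
  }
  if (!any(m))
    stop("bone mask is empty for threshold window [", cfg$hu_lo, ", ",
         cfg$hu_hi, "] HU")
  m
}

#' Mutual information between two images (nats)
#'
#' Dense joint-histogram estimate over the masked voxels:
#' `MI = H(A) + H(B) - H(A, B)`, with equal-width bins spanning each
#' image's masked intensity range. Pairs with a missing (out-of-grid)
#' sample are excluded. Symmetric in its arguments and never negative up to
#' floating-point round-off.
#'
#' @param a,b numeric arrays/vectors or [volume_image()]s on the same grid
#' @param mask optional logical array/vector selecting voxels
#' @param n_bins histogram bins per channel
#' @return MI in nats (a constant image under the mask gives 0 with a
#'   warning)
#' @export
mutual_information <- function(a, b, mask = NULL, n_bins = 64L) {
  av <- if (inherits(a, "volume_image")) as.vector(a$data) else as.vector(a)
  bv <- if (inherits(b, "volume_image")) as.vector(b$data) else as.vector(b)
  if (length(av) != length(bv)) stop("images must share a grid")
  if (!is.null(mask)) {
    mask <- as.vector(mask)
    av <- av[mask]; bv <- bv[mask]
  }
  ok <- !is.na(av) & !is.na(bv)
  av <- av[ok]; bv <- bv[ok]
  if (length(av) == 0L) stop("mask selects no valid voxel pairs")
  .mi_core(av, bv, n_bins)
}

.mi_core <- function(av, bv, n_bins) {
  ra <- range(av); rb <- range(bv)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    warning("constant image under mask: mutual information is 0")
    return(0)
  }
  ia <- pmin(n_bins, 1L + floor((av - ra[1]) / (ra[2] - ra[1]) * n_bins))
  ib <- pmin(n_bins, 1L + floor((bv - rb[1]) / (rb[2] - rb[1]) * n_bins))
  joint <- tabulate((ia - 1L) * n_bins + ib, nbins = n_bins * n_bins)
  n <- length(av)
  p <- joint[joint > 0] / n
  hab <- -sum(p * log(p))
  pa <- tabulate(ia, nbins = n_bins) / n
  pb <- tabulate(ib, nbins = n_bins) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  max(0, ha + hb - hab)
}

.nm_control <- function(cfg) {
  list(fnscale = -1, maxit = cfg$max_iter, reltol = cfg$ftol,
       parscale = c(2, 2, 2, 1, 1, 1))
}

# One Nelder-Mead run plus a restart from the incumbent (a fresh simplex
# around the current optimum escapes premature shrinkage). The discrete
# joint histogram makes MI exactly flat under sub-bin shifts; an
# infinitesimal quadratic pull toward the start (1e-6 nats/mm^2, orders of
# magnitude below any real MI difference) breaks those ties so plateaus
# resolve toward the initial estimate instead of an arbitrary vertex.
.simplex_maximize <- function(par, fn, cfg, fixed_roll = FALSE) {
  ctl <- .nm_control(cfg)
  par0 <- par
  fn_tb <- function(p) fn(p) - 1e-6 * sum((p - par0)^2)
  if (fixed_roll) {
    ctl$parscale <- ctl$parscale[1:5]
    wrap <- function(p) fn_tb(c(p, 0))
    par <- par[1:5]
  } else wrap <- fn_tb
  o1 <- optim(par, wrap, method = "Nelder-Mead", control = ctl)
  o2 <- optim(o1$par, wrap, method = "Nelder-Mead", control = ctl)
  best <- if (o2$value >= o1$value) o2 else o1
  p <- if (fixed_roll) c(best$par, 0) else best$par
  list(par = p, value = best$value,
       counts = sum(o1$counts[1], o2$counts[1], na.rm = TRUE),
       converged = (o2$convergence == 0))
}

.registration_result <- function(par, value, n_eval, converged) {
  structure(list(params = .as_six_dof(par), final_metric = value,
                 n_evaluations = n_eval, converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: MI = %.4f nats after %d evaluations%s\n",
    x$final_metric, x$n_evaluations,
    if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}

#' Rigid 3D auto-registration (6 DoF, bone-thresholded mutual information)
#'
#' Finds the six-degree-of-freedom rigid transform maximizing mutual
#' information between the moving volume — resampled by trilinear
#' interpolation under each candidate transform — and the reference volume,
#' evaluated over the reference's bone-thresholded voxels. Optimization is
#' Nelder-Mead downhill simplex (initial steps 2 mm / 1 degree via parameter
#' scaling, one restart from the incumbent), optionally preceded by a
#' x2-downsampled level. Fully deterministic for fixed inputs and config.
#'
#' A volume produced by [transform_volume()] with parameters `p` registered
#' back to its source recovers `p`.
#'
#' @param moving,reference [volume_image()]s in HU on overlapping grids
#' @param cfg a [registration_config()]
#' @param center rotation centre; defaults to the reference volume centre
#' @return a `registration_result` (fields `params`, `final_metric`,
#'   `n_evaluations`, `converged`)
#' @export
register_rigid_3d <- function(moving, reference,
                              cfg = registration_config(),
                              center = volume_center(reference)) {
  mask <- bone_mask(reference, cfg)
  init <- as.numeric(cfg$init)
  n_eval <- 0L
  if (cfg$multires_levels == 2L) {
    ref2 <- downsample_volume(reference)
    mov2 <- downsample_volume(moving)
    cfg2 <- cfg; cfg2$multires_levels <- 1L
    # the downsampled reference blends bone with neighbours; widen the
    # window downward so averaged bone voxels stay in the mask
    cfg2$hu_lo <- min(cfg$hu_lo, (cfg$hu_lo + 40) / 2)
    coarse <- register_rigid_3d(mov2, ref2, cfg2, center = center)
    init <- as.numeric(coarse$params)
    n_eval <- coarse$n_evaluations
  }
  if (cfg$mask_dilate_vox > 0L)
    mask <- .dilate_mask(mask, cfg$mask_dilate_vox)
  widx <- which(mask)
  ref_vals <- as.vector(reference$data)[widx]
  coords <- voxel_coordinates(reference, which = widx)
  fn <- function(p) {
    m <- build_matrix(.as_six_dof(p), center)
    vals <- sample_volume(moving, apply_to_points(m, coords))
    ok <- !is.na(vals)
    if (sum(ok) < 16L) return(-1e6)
    .mi_core_quiet(ref_vals[ok], vals[ok], cfg$n_bins)
  }
  o <- .simplex_maximize(init, fn, cfg)
  .registration_result(o$par, o$value, n_eval + o$counts, o$converged)
}

.mi_core_quiet <- function(av, bv, n_bins) {
  suppressWarnings(.mi_core(av, bv, n_bins))
}

# box dilation by r voxels (separable along the three axes)
.dilate_mask <- function(m, r) {
  for (ax in 1:3) for (i in seq_len(r))
    m <- m | .shift_arr3(m, ax, 1L) | .shift_arr3(m, ax, -1L)
  m
}

#' Parallel-ray projection of a volume (DRR stand-in)
#'
#' Computes a digitally-reconstructed-radiograph-like image by summing
#' attenuation (HU + 1000, clamped at 0) along parallel rays: frontal rays
#' run along the P-A axis (the 0-degree view), lateral rays along R-L (the
#' 90-degree view). Pixel spacing and origin are inherited from the two
#' in-plane axes.
#'
#' @param vol a [volume_image()] in HU
#' @param direction `"frontal"` or `"lateral"`
#' @return object of class `projection_image` with fields `data` (2D
#'   matrix), `spacing`, `origin`, `axes` (names of the in-plane patient
#'   axes) and `direction`
#' @export
project_drr <- function(vol, direction = c("frontal", "lateral")) {
  direction <- match.arg(direction)
  att <- pmax(vol$data + 1000, 0)
  if (direction == "frontal") {
    img <- apply(att, c(1, 3), sum) * vol$spacing[2]
    keep <- c(1L, 3L); axes <- c("RL", "IS")
  } else {
    img <- apply(att, c(2, 3), sum) * vol$spacing[1]
    keep <- c(2L, 3L); axes <- c("PA", "IS")
  }
  structure(list(data = img, spacing = vol$spacing[keep],
                 origin = vol$origin[keep], axes = axes,
                 direction = direction),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat("projection_image (", x$direction, "): ",
      paste(dim(x$data), collapse = " x "), " pixels (",
      paste(x$axes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Rigid 2D positioning against orthogonal projections (5 DoF)
#'
#' Emulates planar setup verification: the moving volume is transformed by
#' candidate parameters, re-projected frontally and laterally, and the sum
#' of the mutual informations between each re-projection and the
#' corresponding fixed projection is maximized. Because planar positioning
#' cannot correct rotation about the inferior-superior axis, roll is frozen
#' at exactly 0 and five parameters are optimized. Both views are coupled
#' through one shared volume transform, as in a single couch correction.
#'
#' @param moving_vol the reference-derived volume being positioned (DRR
#'   source), a [volume_image()]
#' @param proj_pair list of two `projection_image`s (frontal and lateral)
#'   of the patient at treatment
#' @param cfg a [registration_config()]
#' @param center rotation centre; defaults to the moving volume centre
#' @return a `registration_result` with `params` having `roll = 0`
#' @export
register_rigid_2d <- function(moving_vol, proj_pair,
                              cfg = registration_config(),
                              center = volume_center(moving_vol)) {
  dirs <- vapply(proj_pair, function(p) p$direction, character(1))
  if (!setequal(dirs, c("frontal", "lateral")))
    stop("`proj_pair` must contain one frontal and one lateral projection")
  fixed_f <- proj_pair[[which(dirs == "frontal")]]
  fixed_l <- proj_pair[[which(dirs == "lateral")]]
  fn <- function(p) {
    tv <- transform_volume(moving_vol, .as_six_dof(p), center = center)
    pf <- project_drr(tv, "frontal")
    pl <- project_drr(tv, "lateral")
    .mi_core_quiet(as.vector(fixed_f$data), as.vector(pf$data), cfg$n_bins) +
      .mi_core_quiet(as.vector(fixed_l$data), as.vector(pl$data), cfg$n_bins)
  }
  init <- as.numeric(cfg$init)
  init[6] <- 0
  o <- .simplex_maximize(init, fn, cfg, fixed_roll = TRUE)
  .registration_result(o$par, o$value, o$counts, o$converged)
}
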