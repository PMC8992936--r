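#' Euclidean distances between a structure transformed by two paired
#' registration matrices
#'
#' The interobserver metric at the heart of the pipeline: every original
#' contour point of the structure is transformed separately by the CT-based
#' (dDRR) and sCT-based (sDRR) registration matrix, and the Euclidean
#' distance between the two images of the same point is recorded. Point
#' correspondence is by index — the same original point under each matrix —
#' never nearest-neighbour matching. A pure relative translation t makes the
#' distance histogram a spike at |t|; identical rotations with differing
#' translations shift that spike; relative rotation spreads it.
#'
#' @param ptv a [structure_set()]
#' @param m_ref_a,m_ref_b `rigid_matrix` registration results for the two
#'   references
#' @param bin_width_mm histogram bin width (default 0.25 mm)
#' @return object of class `distance_report`: `per_point_distances` (mm,
#'   structure point order), `mean`, `sd`, `max` (mm), `histogram`
#'   (`breaks`, `counts`)
#' @export
paired_ptv_distances <- function(ptv, m_ref_a, m_ref_b,
                                 bin_width_mm = 0.25) {
  pts <- structure_points(ptv)
  if (is.null(pts) || nrow(pts) == 0L) stop("structure has no points")
  pa <- apply_to_points(m_ref_a, pts)
  pb <- apply_to_points(m_ref_b, pts)
  d <- sqrt(rowSums((pa - pb)^2))
  hi <- max(ceiling(max(d)), bin_width_mm)
  breaks <- seq(0, hi + bin_width_mm, by = bin_width_mm)
  counts <- graphics::hist(d, breaks = breaks, plot = FALSE)$counts
  structure(list(per_point_distances = d,
                 mean = mean(d), sd = stats::sd(d), max = max(d),
                 histogram = list(breaks = breaks, counts = counts)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf(
    "distance_report: %d points, mean %.2f +/- %.2f mm, max %.2f mm\n",
    length(x$per_point_distances), x$mean,
    if (is.na(x$sd)) 0 else x$sd, x$max))
  invisible(x)
}

#' Rasterize a planar-contour structure to a binary volume
#'
#' Voxel centres are tested against the contour polygon of the nearest
#' contour plane (within half the inter-plane gap beyond the extreme
#' planes). Used to evaluate Dice overlap of registered structures.
#'
#' @param s a [structure_set()] with axial planar contours
#' @param grid_spacing_mm isotropic voxel size (default 1 mm)
#' @param margin_mm padding added around the structure bounding box
#' @return a [volume_image()] with 0/1 values
#' @export
rasterize_structure <- function(s, grid_spacing_mm = 1, margin_mm = 2) {
  pts <- structure_points(s)
  if (is.null(pts) || nrow(pts) == 0L) stop("structure has no points")
  for (ct in s$contours) .check_simple_polygon(ct)
  zs <- vapply(s$contours, function(ct) ct[1, 3], numeric(1))
  ord <- order(zs)
  zs <- zs[ord]
  contours <- s$contours[ord]
  gap <- if (length(zs) > 1) max(diff(zs)) else grid_spacing_mm
  lo <- apply(pts, 2, min) - margin_mm
  hi <- apply(pts, 2, max) + margin_mm
  lo[3] <- min(zs) - gap / 2
  hi[3] <- max(zs) + gap / 2
  h <- grid_spacing_mm
  nvox <- pmax(2L, as.integer(ceiling((hi - lo) / h)) + 1L)
  origin <- lo
  xs <- origin[1] + (seq_len(nvox[1]) - 1) * h
  ys <- origin[2] + (seq_len(nvox[2]) - 1) * h
  zvals <- origin[3] + (seq_len(nvox[3]) - 1) * h
  xy <- cbind(rep(xs, times = nvox[2]), rep(ys, each = nvox[1]))
  a <- array(0, nvox)
  for (k in seq_len(nvox[3])) {
    dz <- abs(zvals[k] - zs)
    j <- which.min(dz)
    if (dz[j] > gap / 2 + 1e-9) next
    ct <- contours[[j]]
    bnd <- rbind(ct[, 1:2], ct[1, 1:2])
    a[, , k] <- as.numeric(mgcv::in.out(bnd, xy))
  }
  volume_image(a, spacing = rep(h, 3), origin = origin)
}

# Reject self-intersecting contours (O(n^2) segment test; contours are
# small). Shared endpoints of neighbouring segments are allowed.
.check_simple_polygon <- function(ct) {
  n <- nrow(ct)
  p <- ct[, 1:2, drop = FALSE]
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    for (j in js) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)))
        stop("self-intersecting contour")
    }
  }
  invisible(TRUE)
}

#' Dice similarity coefficient of two binary volumes
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`, symmetric, 1 for identical and
#' 0 for disjoint masks.
#'
#' @param a,b binary volumes ([volume_image()]s or logical/0-1 arrays) on
#'   the same grid
#' @return object of class `overlap_report`: `dsc`, `voxel_counts`
#'   (`a`, `b`, `intersection`)
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "volume_image")) a$data else a
  bv <- if (inherits(b, "volume_image")) b$data else b
  if (!identical(dim(av), dim(bv))) stop("masks must share a grid")
  av <- av > 0; bv <- bv > 0
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0L) stop("both masks are empty")
  ni <- sum(av & bv)
  structure(list(dsc = 2 * ni / (na + nb),
                 voxel_counts = c(a = na, b = nb, intersection = ni)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: DSC = %.4f (|A| = %d, |B| = %d, |A&B| = %d)\n",
              x$dsc, x$voxel_counts["a"], x$voxel_counts["b"],
              x$voxel_counts["intersection"]))
  invisible(x)
}

#' Dice overlap of two registered copies of a structure
#'
#' Convenience wrapper: rasterizes the structure under each registration
#' matrix on a common grid and computes the volumetric 3D Dice coefficient
#' (the default; a 2D frontal-projection variant is available since planar
#' workflows may judge overlap on the projected outline).
#'
#' @param ptv a [structure_set()]
#' @param m_ref_a,m_ref_b `rigid_matrix` registration results
#' @param grid_spacing_mm rasterization voxel size (default 1 mm)
#' @param projected if `TRUE`, compute 2D Dice of the frontal (x-z)
#'   projections of the rasterized volumes instead of 3D
#' @return an `overlap_report`
#' @export
registered_ptv_dice <- function(ptv, m_ref_a, m_ref_b, grid_spacing_mm = 1,
                                projected = FALSE) {
  sa <- transform_structure(ptv, m_ref_a)
  sb <- transform_structure(ptv, m_ref_b)
  # common grid: rasterize each on its own grid, then resample B onto A
  ra <- .rasterize_any_orientation(sa, grid_spacing_mm)
  rb <- .rasterize_any_orientation(sb, grid_spacing_mm, template = ra)
  if (projected) {
    pa <- apply(ra$data, c(1, 3), max)
    pb <- apply(rb$data, c(1, 3), max)
    return(dice(array(pa, c(dim(pa), 1)), array(pb, c(dim(pb), 1))))
  }
  dice(ra, rb)
}

# Rasterize a (possibly rotated, hence non-planar) structure by point-cloud
# membership: voxel centres inside the transformed ellipsoid-like hull are
# found via inverse-transforming the grid is not available generically, so
# we use the convex-hull-free approach of rasterizing in the structure's
# own frame when planar, else nearest-slice after re-slicing points by z.
.rasterize_any_orientation <- function(s, h, template = NULL) {
  pts <- structure_points(s)
  planar <- all(vapply(s$contours,
                       function(ct) diff(range(ct[, 3])) < 1e-6, logical(1)))
  if (planar && is.null(template)) return(rasterize_structure(s, h))
  # generic path: re-slice the point cloud into axial bands and build
  # per-band convex outlines (structures here are convex ellipsoids)
  if (is.null(template)) {
    lo <- apply(pts, 2, min) - 2; hi <- apply(pts, 2, max) + 2
    nvox <- pmax(2L, as.integer(ceiling((hi - lo) / h)) + 1L)
    template <- volume_image(array(0, nvox), rep(h, 3), lo)
  }
  d <- dim(template$data)
  zvals <- template$origin[3] + (seq_len(d[3]) - 1) * template$spacing[3]
  xs <- template$origin[1] + (seq_len(d[1]) - 1) * template$spacing[1]
  ys <- template$origin[2] + (seq_len(d[2]) - 1) * template$spacing[2]
  xy <- cbind(rep(xs, times = d[2]), rep(ys, each = d[1]))
  band <- max(h, diff(range(pts[, 3])) / max(8, length(s$contours)))
  a <- array(0, d)
  for (k in seq_len(d[3])) {
    sel <- abs(pts[, 3] - zvals[k]) <= band
    if (sum(sel) < 3L) next
    q <- pts[sel, 1:2, drop = FALSE]
    hull <- grDevices::chull(q)
    bnd <- rbind(q[hull, , drop = FALSE], q[hull[1], ])
    a[, , k] <- as.numeric(mgcv::in.out(bnd, xy))
  }
  volume_image(a, template$spacing, template$origin)
}

#' Per-case summary of interobserver distance reports
#'
#' Reproduces the per-case table of the interobserver evaluation: the mean
#' and SD over observers of each observer's mean distance, plus the
#' worst-case observer (largest per-observer mean) with that observer's
#' mean +/- SD and the global maximum distance across observers.
#'
#' @param reports list of `distance_report`s, one per observer (names used
#'   as observer labels when present)
#' @return list: `n_observers`, `mean_of_means`, `sd_of_means`,
#'   `worst_observer`, `worst_mean`, `worst_sd`, `max_distance`
#' @export
observer_summary <- function(reports) {
  if (length(reports) == 0L) stop("need at least one observer report")
  means <- vapply(reports, function(r) r$mean, numeric(1))
  sds <- vapply(reports, function(r) r$sd, numeric(1))
  maxs <- vapply(reports, function(r) r$max, numeric(1))
  w <- which.max(means)
  labels <- names(reports)
  if (is.null(labels)) labels <- as.character(seq_along(reports))
  list(n_observers = length(reports),
       mean_of_means = mean(means),
       sd_of_means = if (length(means) > 1) stats::sd(means) else 0,
       worst_observer = labels[w],
       worst_mean = unname(means[w]),
       worst_sd = if (is.na(sds[w])) 0 else unname(sds[w]),
       max_distance = max(maxs))
}
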