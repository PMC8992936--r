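#' 3D scalar volume in patient coordinates
#'
#' A `volume_image` is a 3D array of scalar values (Hounsfield Units for CT
#' data) on a regular grid. Array dimension 1 runs along the R-L (x) axis,
#' dimension 2 along P-A (y) and dimension 3 along I-S (z). The world
#' position of voxel `(i, j, k)` (1-based) is `origin + (c(i,j,k) - 1) *
#' spacing`, in mm.
#'
#' @param data 3D numeric array of voxel values.
#' @param spacing numeric(3), voxel spacing in mm per axis (all > 0).
#' @param origin numeric(3), world position (mm) of the first voxel centre.
#'   Defaults to centring the volume on the world origin, which then acts as
#'   the plan isocenter.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three finite positive values (mm)")
  if (is.null(origin)) origin <- -(dim(data) - 1) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("volume_image:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm\n  value range [", paste(signif(range(x$data), 5), collapse = ", "),
      "], origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n")
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' World coordinate of the volume centre (default isocenter)
#' @param vol a `volume_image`
#' @return numeric(3) mm
#' @export
volume_center <- function(vol) {
  vol$origin + (dim(vol$data) - 1) * vol$spacing / 2
}

#' World coordinates (mm) of every voxel centre, or of a subset
#' @param vol a `volume_image`
#' @param which optional integer vector of linear voxel indices
#' @return n x 3 matrix of mm coordinates
#' @export
voxel_coordinates <- function(vol, which = NULL) {
  d <- dim(vol$data)
  if (is.null(which)) which <- seq_len(prod(d))
  which <- as.integer(which) - 1L
  i <- which %% d[1]
  j <- (which %/% d[1]) %% d[2]
  k <- which %/% (d[1] * d[2])
  cbind(vol$origin[1] + i * vol$spacing[1],
        vol$origin[2] + j * vol$spacing[2],
        vol$origin[3] + k * vol$spacing[3])
}

#' Sample a volume at arbitrary world points by trilinear interpolation
#'
#' Points falling outside the voxel-centre grid return `NA` unless `fill`
#' is given, so that out-of-grid samples can be excluded from similarity
#' histograms rather than padded.
#'
#' @param vol a `volume_image`
#' @param points n x 3 matrix of world coordinates (mm)
#' @param fill value used for out-of-grid points (default `NA`)
#' @return numeric vector of length n
#' @export
sample_volume <- function(vol, points, fill = NA_real_) {
  points <- as.matrix(points)
  idx <- sweep(sweep(points, 2, vol$origin, "-"), 2, vol$spacing, "/")
  out <- .trilinear_cpp(as.double(vol$data), dim(vol$data), idx)
  if (!is.na(fill)) out[is.na(out)] <- fill
  out
}

# Separable truncated-Gaussian convolution along one array axis.
# Kernel rows renormalised near the edges (no implicit padding value).
.blur_axis <- function(a, sigma_vox, axis) {
  if (sigma_vox <= 0) return(a)
  n <- dim(a)[axis]
  r <- max(1L, ceiling(3 * sigma_vox))
  offs <- (-r):r
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (o in seq_along(offs)) {
    src <- seq_len(n) + offs[o]
    ok <- src >= 1 & src <= n
    K[cbind(which(ok), src[ok])] <- K[cbind(which(ok), src[ok])] + k[o]
  }
  K <- K / rowSums(K)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- K %*% matrix(ap, nrow = dp[1])
  aperm(array(m, dp), order(perm))
}

#' Gaussian-blur a volume (separable, sigma in mm)
#' @param vol a `volume_image`
#' @param sigma_mm scalar or per-axis Gaussian standard deviation in mm
#' @return blurred `volume_image` on the same grid
#' @export
blur_volume <- function(vol, sigma_mm) {
  sigma_mm <- rep_len(as.numeric(sigma_mm), 3L)
  if (any(sigma_mm < 0)) stop("`sigma_mm` must be >= 0")
  a <- vol$data
  for (ax in 1:3) a <- .blur_axis(a, sigma_mm[ax] / vol$spacing[ax], ax)
  volume_image(a, vol$spacing, vol$origin)
}

#' Downsample a volume by 2 in each axis (block average)
#' @param vol a `volume_image`
#' @return a `volume_image` with halved grid and doubled spacing
#' @export
downsample_volume <- function(vol) {
  d <- dim(vol$data)
  d2 <- d %/% 2L
  if (any(d2 < 2L)) stop("volume too small to downsample")
  a <- vol$data[seq_len(2 * d2[1]), seq_len(2 * d2[2]), seq_len(2 * d2[3])]
  idx <- function(n) rep(seq_len(n), each = 2L)
  g <- array(0, d2)
  # accumulate the 8 voxels of each 2x2x2 block
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    g <- g + a[seq(1 + dx, 2 * d2[1], by = 2),
               seq(1 + dy, 2 * d2[2], by = 2),
               seq(1 + dz, 2 * d2[3], by = 2)]
  volume_image(g / 8, vol$spacing * 2,
               vol$origin + vol$spacing / 2)
}

#' Resample a volume under a rigid 6-DoF motion of the imaged anatomy
#'
#' The anatomy is moved by `params` (rotation about `center`, then
#' translation): the output voxel at world position x takes the value of the
#' input volume at the pre-image of x under that motion. Registering the
#' result back to the original volume therefore recovers `params`.
#'
#' @param vol a `volume_image`
#' @param params a [six_dof()] parameter set
#' @param center rotation centre (mm); defaults to the volume centre
#' @param fill value for points mapped outside the input grid
#' @return a `volume_image` on the same grid as `vol`
#' @export
transform_volume <- function(vol, params, center = volume_center(vol),
                             fill = -1000) {
  m <- build_matrix(params, center)
  minv <- invert_matrix(m)
  pts <- voxel_coordinates(vol)
  vals <- sample_volume(vol, apply_to_points(minv, pts), fill = fill)
  volume_image(array(vals, dim(vol$data)), vol$spacing, vol$origin)
}
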