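#' Synthetic dense displacement fields with analytic Jacobians
#'
#' Generates per-voxel 3D displacement fields (mm) on a volume grid for
#' testing deformation quality assurance. Each kind carries a closed-form
#' Jacobian-determinant function of the mapping `x -> x + u(x)` as metadata,
#' so finite-difference estimates can be checked against an exact oracle:
#'
#' * `identity`: u = 0, JD = 1 everywhere.
#' * `affine_scale`: u = (S - I)(x - x0) for diagonal scales
#'   `params$scale = c(sx, sy, sz)`; JD = sx*sy*sz everywhere.
#' * `gaussian_bump`: u_z = A exp(-|x - x0|^2 / (2 s^2)); the Jacobian is a
#'   rank-one update, JD = 1 + du_z/dz, smooth and positive for small A.
#' * `folding`: the same bump with amplitude large enough that
#'   min JD = 1 - A exp(-1/2) / s < 0, i.e. a physically unrealistic
#'   (folding) deformation is guaranteed.
#'
#' @param grid a [volume_image()] or list with `dim`, `spacing`, `origin`
#'   describing the voxel grid
#' @param kind one of `"identity"`, `"affine_scale"`, `"gaussian_bump"`,
#'   `"folding"`
#' @param params list of kind-specific parameters: `scale` (affine_scale);
#'   `amplitude_mm`, `sigma_mm`, `center` (bump kinds)
#' @param seed unused by the deterministic kinds; kept for interface
#'   uniformity with the other generators
#' @return object of class `displacement_field`: fields `u` (array
#'   `c(dim, 3)`, mm), `spacing`, `origin`, `kind`, `params`,
#'   `jd_analytic(points)` and (bump kinds) `jd_min_analytic`
#' @export
make_deformation <- function(grid, kind = c("identity", "affine_scale",
                                            "gaussian_bump", "folding"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (inherits(grid, "volume_image"))
    grid <- list(dim = dim(grid$data), spacing = grid$spacing,
                 origin = grid$origin)
  d <- as.integer(grid$dim)
  spacing <- as.numeric(grid$spacing)
  origin <- as.numeric(grid$origin)
  ctr <- origin + (d - 1) * spacing / 2
  pts <- .grid_points(d, spacing, origin)

  if (kind == "identity") {
    u <- array(0, c(d, 3))
    jd <- function(points) rep(1, nrow(as.matrix(points)))
    jd_min <- 1
  } else if (kind == "affine_scale") {
    s <- params$scale
    if (is.null(s) || length(s) != 3L || any(!is.finite(s)))
      stop("affine_scale requires params$scale = c(sx, sy, sz)")
    u <- array(0, c(d, 3))
    for (ax in 1:3)
      u[, , , ax] <- array((s[ax] - 1) * (pts[, ax] - ctr[ax]), d)
    jd <- local({
      pj <- prod(s)
      function(points) rep(pj, nrow(as.matrix(points)))
    })
    jd_min <- prod(s)
  } else {
    s <- if (is.null(params$sigma_mm)) 10 else params$sigma_mm
    x0 <- if (is.null(params$center)) ctr else as.numeric(params$center)
    A <- params$amplitude_mm
    if (is.null(A))
      A <- if (kind == "folding") 3 * s * exp(0.5) else 0.25 * s
    if (kind == "folding" && A <= s * exp(0.5))
      stop("folding requires amplitude_mm > sigma_mm * exp(1/2) ",
           "so that min JD < 0")
    phi <- exp(-((pts[, 1] - x0[1])^2 + (pts[, 2] - x0[2])^2 +
                   (pts[, 3] - x0[3])^2) / (2 * s^2))
    u <- array(0, c(d, 3))
    u[, , , 3] <- array(A * phi, d)
    jd <- local({
      A. <- A; s. <- s; x0. <- x0
      function(points) {
        p <- as.matrix(points)
        ph <- exp(-((p[, 1] - x0.[1])^2 + (p[, 2] - x0.[2])^2 +
                      (p[, 3] - x0.[3])^2) / (2 * s.^2))
        1 - A. * (p[, 3] - x0.[3]) / s.^2 * ph
      }
    })
    jd_min <- 1 - A * exp(-0.5) / s
  }
  structure(list(u = u, spacing = spacing, origin = origin, kind = kind,
                 params = params, jd_analytic = jd,
                 jd_min_analytic = jd_min),
            class = "displacement_field")
}

.grid_points <- function(d, spacing, origin) {
  i <- seq_len(d[1]) - 1
  j <- seq_len(d[2]) - 1
  k <- seq_len(d[3]) - 1
  cbind(rep(origin[1] + i * spacing[1], times = d[2] * d[3]),
        rep(rep(origin[2] + j * spacing[2], each = d[1]), times = d[3]),
        rep(origin[3] + k * spacing[3], each = d[1] * d[2]))
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("displacement_field (", x$kind, "): ",
      paste(dim(x$u)[1:3], collapse = " x "), " voxels, max |u| = ",
      signif(max(abs(x$u)), 4), " mm\n", sep = "")
  invisible(x)
}
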