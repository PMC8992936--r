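#' Six-degree-of-freedom rigid setup parameters
#'
#' Couch-correction parameterization used throughout: translations in mm
#' along the patient axes (tx: R-L, ty: P-A, tz: I-S) and rotations in
#' degrees about those axes (pitch about R-L, yaw about P-A, roll about I-S).
#' The pipeline targets the small-displacement regime of setup corrections;
#' rotations must satisfy |angle| < 90 degrees.
#'
#' @param tx,ty,tz translations (mm)
#' @param pitch,yaw,roll rotations (degrees)
#' @return named numeric of class `six_dof`
#' @export
six_dof <- function(tx = 0, ty = 0, tz = 0, pitch = 0, yaw = 0, roll = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, pitch = pitch, yaw = yaw, roll = roll)
  if (any(!is.finite(p))) stop("six_dof parameters must all be finite")
  if (any(abs(p[4:6]) >= 90))
    stop("rotations must satisfy |angle| < 90 degrees")
  structure(as.numeric(p), names = names(p), class = "six_dof")
}

.as_six_dof <- function(p) {
  if (inherits(p, "six_dof")) return(p)
  p <- as.numeric(p)
  if (length(p) != 6L) stop("expected 6 parameters (tx, ty, tz, pitch, yaw, roll)")
  six_dof(p[1], p[2], p[3], p[4], p[5], p[6])
}

#' @export
print.six_dof <- function(x, ...) {
  cat(sprintf("six_dof: t = (%.3f, %.3f, %.3f) mm, rot = (%.3f, %.3f, %.3f) deg\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

.rot3 <- function(pitch, yaw, roll) {
  d2r <- pi / 180
  ax <- pitch * d2r; ay <- yaw * d2r; az <- roll * d2r
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  # extrinsic fixed-axes composition Rz(roll) %*% Ry(yaw) %*% Rx(pitch)
  matrix(c(cz * cy, sz * cy, -sy,
           cz * sy * sx - sz * cx, sz * sy * sx + cz * cx, cy * sx,
           cz * sy * cx + sz * sx, sz * sy * cx - cz * sx, cy * cx),
         nrow = 3)
}

#' Build a homogeneous rigid matrix from 6-DoF parameters
#'
#' The rotation (extrinsic, fixed patient axes, composed as
#' Rz(roll) Ry(yaw) Rx(pitch)) is applied about `center`, then the
#' translation: `x' = R (x - c) + c + t`. All-zero parameters give the
#' identity. The centre is carried with the matrix because two matrices with
#' identical 4x4 entries but different centres decompose into different
#' translation parameters.
#'
#' @param p a [six_dof()] (or numeric length 6 in its order)
#' @param center rotation centre, numeric(3) mm (default the origin,
#'   i.e. the plan isocenter)
#' @return object of class `rigid_matrix` with fields `mat` (4x4) and
#'   `center`
#' @export
build_matrix <- function(p, center = c(0, 0, 0)) {
  p <- .as_six_dof(p)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be three finite values (mm)")
  R <- .rot3(p[4], p[5], p[6])
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center + p[1:3] - R %*% center
  structure(list(mat = m, center = center), class = "rigid_matrix")
}

.check_rigid <- function(m, tol = 1e-9) {
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > sqrt(tol) * 1e3 ||
      abs(det(R) - 1) > 1e-6)
    stop("matrix is not a rigid (proper orthonormal) transform")
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > tol))
    stop("last row of a homogeneous rigid matrix must be (0,0,0,1)")
  invisible(TRUE)
}

#' @export
print.rigid_matrix <- function(x, ...) {
  cat("rigid_matrix (rotation centre", paste(signif(x$center, 4), collapse = ", "),
      "mm):\n")
  print(round(x$mat, 6))
  invisible(x)
}

#' Invert a rigid matrix
#' @param m a `rigid_matrix`
#' @return the inverse `rigid_matrix` (same rotation centre)
#' @export
invert_matrix <- function(m) {
  R <- t(m$mat[1:3, 1:3])
  inv <- diag(4)
  inv[1:3, 1:3] <- R
  inv[1:3, 4] <- -R %*% m$mat[1:3, 4]
  structure(list(mat = inv, center = m$center), class = "rigid_matrix")
}

#' Compose two rigid matrices (`a` applied after `b`)
#' @param a,b `rigid_matrix` objects
#' @return `rigid_matrix` with `a$center` as rotation centre
#' @export
compose_matrices <- function(a, b) {
  structure(list(mat = a$mat %*% b$mat, center = a$center),
            class = "rigid_matrix")
}

#' Apply a rigid matrix to 3D points
#' @param m a `rigid_matrix`
#' @param pts n x 3 matrix (or length-3 vector) of mm coordinates
#' @return n x 3 matrix of transformed coordinates
#' @export
apply_to_points <- function(m, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop("points must be n x 3")
  if (any(!is.finite(pts))) stop("points must be finite")
  out <- pts %*% t(m$mat[1:3, 1:3])
  sweep(out, 2, m$mat[1:3, 4], "+")
}

#' Decompose a rigid matrix into 6-DoF parameters
#'
#' Inverse of [build_matrix()] within the |rotation| < 90 degree regime.
#' Near gimbal lock (|yaw| approaching 90 degrees) the pitch/roll split is
#' ill-conditioned and an error is raised.
#'
#' @param m a `rigid_matrix`
#' @param center rotation centre to decompose about (default the centre
#'   stored in `m`)
#' @return a [six_dof()]
#' @export
params_from_matrix <- function(m, center = m$center) {
  .check_rigid(m$mat)
  R <- m$mat[1:3, 1:3]
  sy <- -R[3, 1]
  if (abs(sy) > 1 - 1e-9)
    stop("yaw at +/-90 degrees: rotation decomposition is degenerate (gimbal lock)")
  r2d <- 180 / pi
  yaw <- asin(sy) * r2d
  pitch <- atan2(R[3, 2], R[3, 3]) * r2d
  roll <- atan2(R[2, 1], R[1, 1]) * r2d
  t <- m$mat[1:3, 4] - center + R %*% center
  six_dof(t[1], t[2], t[3], pitch, yaw, roll)
}

#' Restrict parameters to the 5 DoF available in 2D positioning
#'
#' Orthogonal-projection (planar) positioning cannot correct rotation about
#' the inferior-superior axis; roll is therefore pinned to zero and the other
#' five parameters pass through unchanged. Idempotent.
#'
#' @param p a [six_dof()]
#' @return a [six_dof()] with `roll = 0`
#' @export
restrict_to_5dof <- function(p) {
  p <- .as_six_dof(p)
  six_dof(p[1], p[2], p[3], p[4], p[5], 0)
}
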