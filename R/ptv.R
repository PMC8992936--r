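#' Structure set: ordered planar contour point lists
#'
#' Mirrors the content of a DICOM-RT Struct structure: a list of planar
#' (axial) contours, each an ordered `n x 3` matrix of `[x, y, z]` mm
#' coordinates in patient space. Point order is significant — the
#' interobserver distance metric relies on index correspondence between the
#' same structure transformed by two registration matrices. Contours are
#' stored open (the closing point is not duplicated).
#'
#' @param contours list of n x 3 numeric matrices, each planar in z
#' @param name structure label
#' @return object of class `structure_set`
#' @export
structure_set <- function(contours, name = "PTV") {
  if (!is.list(contours) || length(contours) == 0L)
    stop("`contours` must be a non-empty list of point matrices")
  contours <- lapply(contours, function(ct) {
    ct <- as.matrix(ct)
    if (ncol(ct) != 3L || nrow(ct) < 3L)
      stop("each contour needs at least 3 points with 3 coordinates")
    if (any(!is.finite(ct))) stop("contour points must be finite")
    # deduplicate an explicitly closed contour
    n <- nrow(ct)
    if (sqrt(sum((ct[1, ] - ct[n, ])^2)) < 1e-9) ct <- ct[-n, , drop = FALSE]
    if (diff(range(ct[, 3])) > 1e-6)
      stop("contours must be planar in z (axial)")
    dimnames(ct) <- NULL
    ct
  })
  structure(list(contours = contours, name = name), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set '", x$name, "': ", length(x$contours), " contours, ",
      sum(vapply(x$contours, nrow, integer(1))), " points\n", sep = "")
  invisible(x)
}

#' All points of a structure as one matrix (contour order preserved)
#' @param s a `structure_set`
#' @return n x 3 matrix of mm coordinates
#' @export
structure_points <- function(s) do.call(rbind, s$contours)

#' Generate an ellipsoidal PTV as a stack of planar contours
#'
#' Slice planes are placed at the midpoints of `n_slices` equal axial slabs
#' spanning the ellipsoid, and each plane carries an elliptical contour
#' sampled at `pts_per_contour` equal angles starting at angle 0 (the +x
#' direction). Two calls with identical parameters produce point-identical
#' structures, giving the index correspondence the distance metric needs.
#'
#' @param center numeric(3) mm
#' @param semi_axes numeric(3) mm (a, b, c), all > 0
#' @param n_slices number of axial contours (>= 2)
#' @param pts_per_contour points per contour (>= 8)
#' @return a [structure_set()]
#' @export
make_ptv <- function(center = c(0, 0, 0), semi_axes = c(20, 20, 20),
                     n_slices = 10L, pts_per_contour = 64L) {
  if (any(semi_axes <= 0)) stop("`semi_axes` must all be > 0")
  if (n_slices < 2L) stop("`n_slices` must be >= 2")
  if (pts_per_contour < 8L) stop("`pts_per_contour` must be >= 8")
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  dz <- (2 * cc) / n_slices
  zoff <- -cc + (seq_len(n_slices) - 0.5) * dz
  ang <- 2 * pi * (seq_len(pts_per_contour) - 1) / pts_per_contour
  contours <- lapply(zoff, function(z) {
    f <- sqrt(max(0, 1 - (z / cc)^2))
    cbind(center[1] + a * f * cos(ang),
          center[2] + b * f * sin(ang),
          center[3] + z)
  })
  structure_set(contours, name = "PTV")
}

#' Apply a rigid matrix to every contour point of a structure
#' @param s a [structure_set()]
#' @param m a `rigid_matrix`
#' @return transformed `structure_set` (note: contours are generally no
#'   longer axial-planar after rotation; point order is preserved)
#' @export
transform_structure <- function(s, m) {
  out <- s
  out$contours <- lapply(s$contours, function(ct) apply_to_points(m, ct))
  class(out) <- "structure_set"
  out
}
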