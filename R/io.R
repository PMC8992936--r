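#' Read / write volumes as NIfTI
#'
#' Volumes round-trip through NIfTI-1 with grid, spacing, origin and —
#' for integer HU data — values preserved bit-exactly. Spacing is stored in
#' `pixdim`, the origin in the qform offset. Displacement fields are
#' written as 4D volumes with the vector component as the fourth dimension.
#'
#' @param vol a [volume_image()] (or `displacement_field` for
#'   [write_field()])
#' @param path file path ending in `.nii` or `.nii.gz`
#' @param datatype NIfTI storage type: `"int16"` for HU volumes,
#'   `"double"` to preserve continuous values exactly
#' @return `read_volume()` returns a [volume_image()];
#'   the writers return `path` invisibly
#' @export
write_volume <- function(vol, path, datatype = "double") {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  storage.mode(a) <- "double"
  volume_image(a, spacing = RNifti::pixdim(img)[1:3], origin = x[1:3, 4])
}

#' @rdname write_volume
#' @export
write_field <- function(vol, path) {
  img <- RNifti::asNifti(vol$u)
  RNifti::pixdim(img) <- c(vol$spacing, 1)
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("field file not found: ", path)
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("not a 3-component displacement field: ", path)
  structure(list(u = a, spacing = RNifti::pixdim(img)[1:3],
                 origin = x[1:3, 4], kind = "file", params = list(),
                 jd_analytic = NULL, jd_min_analytic = NULL),
            class = "displacement_field")
}

#' Read / write structure sets as JSON
#'
#' The canonical interchange format mirrors DICOM-RT Struct content:
#' a structure name plus a list of contours, each an ordered list of
#' `[x, y, z]` mm triples in patient coordinates. Point order is preserved
#' exactly — index correspondence is what the paired-distance metric relies
#' on. Contours with fewer than 3 points are rejected.
#'
#' @param s a [structure_set()]
#' @param path JSON file path
#' @return `read_structure()` returns a [structure_set()]
#' @export
write_structure <- function(s, path) {
  obj <- list(name = s$name,
              contours = lapply(s$contours, function(ct)
                unname(apply(ct, 1, function(p) p, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$contours) || length(obj$contours) == 0L)
    stop("invalid structure JSON (no $contours): ", path)
  contours <- lapply(seq_along(obj$contours), function(i) {
    ct <- obj$contours[[i]]
    if (length(ct) < 3L)
      stop("contour $contours[", i, "] has fewer than 3 points in ", path)
    mat <- t(vapply(ct, function(p) {
      v <- as.numeric(unlist(p))
      if (length(v) != 3L || any(!is.finite(v)))
        stop("malformed point in $contours[", i, "] of ", path)
      v
    }, numeric(3)))
    mat
  })
  structure_set(contours,
                name = if (is.null(obj$name)) "structure" else obj$name)
}

#' Read / write rigid matrices as JSON (row-major 4x4 + rotation centre)
#' @param m a `rigid_matrix`
#' @param path JSON file path
#' @return `read_matrix()` returns a `rigid_matrix`
#' @export
write_matrix <- function(m, path) {
  obj <- list(matrix = as.vector(t(m$mat)), rotation_center = m$center)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- matrix(as.numeric(obj$matrix), 4, 4, byrow = TRUE)
  .check_rigid(mat)
  structure(list(mat = mat, center = as.numeric(obj$rotation_center)),
            class = "rigid_matrix")
}

#' Write / read paired-registration tables as CSV
#'
#' Long format with the canonical columns `case`, `observer`, `modality`,
#' `reference`, `tx`, `ty`, `tz`, `pitch`, `yaw`, `roll` (mm / degrees), so
#' the per-direction summary tables are one reshape away.
#'
#' @param tab a data.frame as from [sample_paired_registrations()]
#' @param path CSV path
#' @return `read_registrations()` returns the data.frame
#' @export
write_registrations <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registrations
#' @export
read_registrations <- function(path) {
  if (!file.exists(path)) stop("registration table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# FNV-1a 32-bit over a string; used to stamp outputs with a config hash
.config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (ch in s) {
    h <- bitwXor(as.integer(h %% 2^31), ch)  # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
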