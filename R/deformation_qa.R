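#' Jacobian-determinant QA of a displacement field
#'
#' Computes the determinant of the Jacobian (JD) of the mapping
#' `x -> x + u(x)`, i.e. `det(I + grad u)`, by finite differences — central
#' in the mask interior, one-sided where a neighbour leaves the mask (so the
#' body surface does not produce spurious gradients), with voxel spacing in
#' mm. A deformation is flagged physically realistic only if the JD is
#' strictly positive everywhere within the mask: JD > 1 means local
#' expansion, JD < 1 contraction, JD <= 0 a non-invertible folding.
#'
#' @param field a `displacement_field` (see [make_deformation()]) or a list
#'   with `u` (array `c(dim, 3)`, mm), `spacing`, `origin`
#' @param mask logical array on the field grid (e.g. the body mask);
#'   `NULL` evaluates everywhere
#' @return object of class `jd_report`: `jd_field` (array, `NA` outside
#'   mask), `min_jd`, `max_jd`, `fraction_nonpositive`, `realistic`
#' @export
jacobian_determinant <- function(field, mask = NULL) {
  u <- field$u
  d <- dim(u)[1:3]
  sp <- field$spacing
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask must match the field grid")
  if (!any(mask)) stop("mask is empty")

  g <- vector("list", 9)  # g[[3*(ax-1)+comp]] = d u_comp / d x_ax
  for (ax in 1:3) {
    fwd <- .shift_arr(u, ax, -1L)   # value at i+1
    bwd <- .shift_arr(u, ax, +1L)   # value at i-1
    m_fwd <- .shift_arr3(mask, ax, -1L)
    m_bwd <- .shift_arr3(mask, ax, +1L)
    both <- m_fwd & m_bwd
    only_f <- m_fwd & !m_bwd
    only_b <- m_bwd & !m_fwd
    for (comp in 1:3) {
      uc <- u[, , , comp]
      fc <- fwd[, , , comp]; bc <- bwd[, , , comp]
      der <- array(0, d)
      der[both] <- (fc[both] - bc[both]) / (2 * sp[ax])
      der[only_f] <- (fc[only_f] - uc[only_f]) / sp[ax]
      der[only_b] <- (uc[only_b] - bc[only_b]) / sp[ax]
      g[[3 * (ax - 1) + comp]] <- der
    }
  }
  # det(I + D) with D[comp, ax] = d u_comp / d x_ax
  a11 <- 1 + g[[1]]; a21 <- g[[2]]; a31 <- g[[3]]
  a12 <- g[[4]]; a22 <- 1 + g[[5]]; a32 <- g[[6]]
  a13 <- g[[7]]; a23 <- g[[8]]; a33 <- 1 + g[[9]]
  jd <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  jd[!mask] <- NA_real_
  vals <- jd[mask]
  fnp <- mean(vals <= 0)
  structure(list(jd_field = jd, min_jd = min(vals), max_jd = max(vals),
                 fraction_nonpositive = fnp, realistic = (fnp == 0)),
            class = "jd_report")
}

# shift array values along `ax` by `by` voxels (by = -1 brings neighbour
# i+1 into position i); vacated border planes replicate the edge value so
# masked one-sided logic, not the pad, decides what is used there.
.shift_arr <- function(u, ax, by) {
  d <- dim(u)[1:3]
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), 1:3)
  src <- pmin(pmax(idx[[ax]] - by, 1L), d[ax])
  idx[[ax]] <- src
  u[idx[[1]], idx[[2]], idx[[3]], idx[[4]], drop = FALSE]
}

.shift_arr3 <- function(m, ax, by) {
  d <- dim(m)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  src <- idx[[ax]] - by
  keep <- src >= 1L & src <= d[ax]
  out <- array(FALSE, d)
  dst <- idx; dst[[ax]] <- idx[[ax]][keep]
  srcl <- idx; srcl[[ax]] <- src[keep]
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[srcl[[1]], srcl[[2]], srcl[[3]]]
  out
}

#' @export
print.jd_report <- function(x, ...) {
  cat(sprintf(
    "jd_report: JD in [%.4f, %.4f], %.2f%% non-positive -> %s\n",
    x$min_jd, x$max_jd, 100 * x$fraction_nonpositive,
    if (x$realistic) "physically realistic" else "UNREALISTIC (folding)"))
  invisible(x)
}

#' Anatomical landmark offsets between two images
#'
#' Each landmark definition names a pair of landmarks and an axis: the
#' within-image distance (signed coordinate difference along `RL`/`PA`/`IS`,
#' or the Euclidean distance) is computed in image A and in image B, and
#' the difference A - B reported — the anatomical-correspondence check
#' applied to a registration's output.
#'
#' @param points_a,points_b labelled n x 3 landmark matrices (row names are
#'   labels) from the two images
#' @param definitions list of definitions, each
#'   `list(name =, labels = c(l1, l2), axis = "RL"|"PA"|"IS"|"euclidean")`;
#'   `NULL` uses the default head-and-neck set matching the phantom's
#'   landmarks
#' @return object of class `landmark_report`: data.frame with `name`,
#'   `axis`, `dist_a`, `dist_b`, `difference` (mm)
#' @export
landmark_offsets <- function(points_a, points_b, definitions = NULL) {
  if (is.null(definitions)) definitions <- default_landmark_definitions()
  axis_col <- c(RL = 1L, PA = 2L, IS = 3L)
  rows <- lapply(definitions, function(def) {
    for (lab in def$labels)
      if (!(lab %in% rownames(points_a)) || !(lab %in% rownames(points_b)))
        stop("landmark label not found in both sets: ", lab)
    pa <- points_a[def$labels, , drop = FALSE]
    pb <- points_b[def$labels, , drop = FALSE]
    within <- function(p) {
      if (def$axis == "euclidean") sqrt(sum((p[1, ] - p[2, ])^2))
      else p[1, axis_col[[def$axis]]] - p[2, axis_col[[def$axis]]]
    }
    da <- within(pa); db <- within(pb)
    data.frame(name = def$name, axis = def$axis,
               dist_a = da, dist_b = db, difference = da - db)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("landmark_report", class(out))
  out
}

#' Default landmark-distance definitions for the phantom's landmark set
#'
#' Horizontal distances map to the R-L axis, vertical distances to I-S,
#' mirroring how bone-landmark distances are read off axial/sagittal CT in
#' head-and-neck QA. Editable: pass your own list to [landmark_offsets()].
#' @return list of definition lists
#' @export
default_landmark_definitions <- function() {
  list(
    list(name = "intercondylar_RL",
         labels = c("mandibular_condyle_left", "mandibular_condyle_right"),
         axis = "RL"),
    list(name = "intermastoid_RL",
         labels = c("mastoid_left", "mastoid_right"), axis = "RL"),
    list(name = "mentum_to_vertebra_IS",
         labels = c("mentum", "anterior_vertebral_body"), axis = "IS"),
    list(name = "c2_canal_to_c4_canal_IS",
         labels = c("spinal_canal_c2", "spinal_canal_c4"), axis = "IS"),
    list(name = "hyoid_to_vertebra_PA",
         labels = c("hyoid", "anterior_vertebral_body"), axis = "PA"),
    list(name = "condyle_to_mastoid_euclidean",
         labels = c("mandibular_condyle_left", "mastoid_left"),
         axis = "euclidean")
  )
}

#' Summary of landmark offsets across cases
#' @param reports list of `landmark_report`s (one per case)
#' @return data.frame `name`, `axis`, `n`, `mean`, `sd` of the differences
#' @export
landmark_offset_summary <- function(reports) {
  all <- do.call(rbind, lapply(reports, as.data.frame))
  key <- interaction(all$name, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    g <- all[key == k, ]
    data.frame(name = g$name[1], axis = g$axis[1], n = nrow(g),
               mean = mean(g$difference),
               sd = if (nrow(g) > 1) stats::sd(g$difference) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reproducibility of repeated landmark placement
#'
#' Distances of each repeat placement to the centroid of all repeats; the
#' mean and maximum of those distances summarize operator placement
#' reproducibility. (An alternative, centroid-free statistic — the mean
#' pairwise distance — is available via `statistic = "pairwise"`.)
#'
#' @param repeats matrix (repeats x 3) or list of length-3 points, repeat
#'   placements of one landmark (>= 2)
#' @param statistic `"centroid"` (default) or `"pairwise"`
#' @return list `mean_mm`, `max_mm`
#' @export
landmark_reproducibility <- function(repeats,
                                     statistic = c("centroid", "pairwise")) {
  statistic <- match.arg(statistic)
  if (is.list(repeats)) repeats <- do.call(rbind, repeats)
  repeats <- as.matrix(repeats)
  if (nrow(repeats) < 2L) stop("need at least 2 repeat placements")
  if (statistic == "centroid") {
    ctr <- colMeans(repeats)
    d <- sqrt(rowSums(sweep(repeats, 2, ctr)^2))
  } else {
    d <- as.vector(stats::dist(repeats))
  }
  list(mean_mm = mean(d), max_mm = max(d))
}
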