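#' Specification of the synthetic head-and-neck CT phantom
#'
#' The phantom emulates a head-and-neck planning CT: an ellipsoidal
#' soft-tissue body surrounded by -1000 HU air, containing analytic bone
#' solids — a skull-like spherical shell, a cervical column of stacked
#' cylinders and a mandible-like arc (half-torus). Analytic solids are used
#' so that masks and volumes have closed-form oracles. Default bone HU sits
#' inside the clinical 200-1700 HU bone-threshold window so bone survives
#' thresholded registration.
#'
#' @param grid_shape integer(3) voxels per axis (all >= 16)
#' @param spacing numeric(3) mm per voxel; default 1.12 x 1.12 mm in-plane
#'   with 2 mm slices, the reconstruction grid typical of head-and-neck CT
#' @param body_axes numeric(3) mm semi-axes of the soft-tissue ellipsoid
#' @param bone_elements list of bone primitives (see Details); `NULL` uses
#'   the default skull/column/mandible set
#' @param hu_soft,hu_bone,hu_air Hounsfield Units of soft tissue, bone, air
#' @param seed integer seed recorded in the spec (the phantom itself is
#'   deterministic; the seed feeds downstream noise generators)
#'
#' @details Bone primitives are lists with a `type` field:
#'   * `shell`: `center` (mm), `r_outer`, `r_inner` (mm)
#'   * `cylinder`: `center` (mm, centre of the cylinder), `radius`, `height`
#'     (mm), axis fixed along I-S
#'   * `arc`: half-torus in an axial plane; `center` (mm), `ring_radius`,
#'     `tube_radius` (mm), spanning the anterior half (y < centre)
#'   Each may carry its own `hu`; otherwise `hu_bone` is used.
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing = c(1.12, 1.12, 2.0),
                         body_axes = c(42, 46, 75),
                         bone_elements = NULL,
                         hu_soft = 40, hu_bone = 900, hu_air = -1000,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("`grid_shape` must be three integers >= 16")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0) || any(!is.finite(spacing)))
    stop("`spacing` must be three positive values (mm)")
  if (length(body_axes) != 3L || any(body_axes <= 0))
    stop("`body_axes` must be three positive semi-axes (mm)")
  if (!(hu_air < hu_soft && hu_soft < hu_bone))
    stop("HU ordering must satisfy hu_air < hu_soft < hu_bone")
  if (is.null(bone_elements)) bone_elements <- .default_bone_elements()
  for (el in bone_elements) {
    hu <- if (is.null(el$hu)) hu_bone else el$hu
    if (hu < 200 || hu > 1700)
      stop("bone element HU must lie within the 200-1700 HU threshold window")
  }
  if (hu_bone < 200 || hu_bone > 1700)
    stop("`hu_bone` must lie within the 200-1700 HU threshold window")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 body_axes = body_axes, bone_elements = bone_elements,
                 hu_soft = hu_soft, hu_bone = hu_bone, hu_air = hu_air,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.default_bone_elements <- function() {
  list(
    list(type = "shell", name = "skull",
         center = c(0, 0, 38), r_outer = 30, r_inner = 25),
    list(type = "cylinder", name = "vertebra_c5",
         center = c(0, 16, -49), radius = 8, height = 14),
    list(type = "cylinder", name = "vertebra_c4",
         center = c(0, 16, -33), radius = 8, height = 14),
    list(type = "cylinder", name = "vertebra_c3",
         center = c(0, 16, -17), radius = 8, height = 14),
    list(type = "cylinder", name = "vertebra_c2",
         center = c(0, 16, -1), radius = 8, height = 14),
    list(type = "arc", name = "mandible",
         center = c(0, -10, 20), ring_radius = 26, tube_radius = 5)
  )
}

#' Closed-form volume (mm^3) of one bone primitive
#' @param el a bone-element list as in [phantom_spec()]
#' @return volume in mm^3
#' @export
bone_element_volume <- function(el) {
  switch(el$type,
    shell = 4 / 3 * pi * (el$r_outer^3 - el$r_inner^3),
    cylinder = pi * el$radius^2 * el$height,
    arc = pi^2 * el$ring_radius * el$tube_radius^2, # half of 2*pi^2*R*r^2
    stop("unknown bone element type: ", el$type))
}

.element_mask <- function(el, x, y, z) {
  c0 <- el$center
  switch(el$type,
    shell = {
      d2 <- (x - c0[1])^2 + (y - c0[2])^2 + (z - c0[3])^2
      d2 <= el$r_outer^2 & d2 >= el$r_inner^2
    },
    cylinder = {
      (x - c0[1])^2 + (y - c0[2])^2 <= el$radius^2 &
        abs(z - c0[3]) <= el$height / 2
    },
    arc = {
      ring <- sqrt((x - c0[1])^2 + (y - c0[2])^2)
      (ring - el$ring_radius)^2 + (z - c0[3])^2 <= el$tube_radius^2 &
        y <= c0[2]
    },
    stop("unknown bone element type: ", el$type))
}

.default_landmarks <- function() {
  rbind(
    mandibular_condyle_right = c(-26, -10, 20),
    mandibular_condyle_left  = c(26, -10, 20),
    mentum                   = c(0, -36, 20),
    mastoid_right            = c(-20, 12, 16),
    mastoid_left             = c(20, 12, 16),
    spinal_canal_c2          = c(0, 16, -1),
    spinal_canal_c4          = c(0, 16, -33),
    hyoid                    = c(0, -20, 0),
    anterior_vertebral_body  = c(0, 8, -1)
  )
}

#' Generate the synthetic head-and-neck phantom CT
#'
#' Rasterizes the analytic body/bone solids of a [phantom_spec()] on its
#' voxel grid (voxel centre membership) and returns the HU volume together
#' with the ground-truth channel used by recovery tests: the (identity)
#' applied transform, labelled anatomical landmark positions, the PTV
#' centre and the body mask (voxels above the -1000 HU air background).
#'
#' @param spec a [phantom_spec()]
#' @return list with elements `volume` (a [volume_image()]) and `truth`
#'   (fields `applied_transform`, `landmark_positions`, `ptv_center`,
#'   `body_mask`)
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  d <- spec$grid_shape
  origin <- -(d - 1) * spec$spacing / 2
  xs <- origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  x <- array(xs, d)
  y <- array(rep(ys, each = d[1]), d)
  z <- array(rep(zs, each = d[1] * d[2]), d)

  body <- (x / spec$body_axes[1])^2 + (y / spec$body_axes[2])^2 +
    (z / spec$body_axes[3])^2 <= 1
  a <- array(spec$hu_air, d)
  a[body] <- spec$hu_soft
  bone_any <- array(FALSE, d)
  for (el in spec$bone_elements) {
    m <- .element_mask(el, x, y, z)
    if (any(m & !body))
      stop("bone element '", if (is.null(el$name)) el$type else el$name,
           "' extends outside the body contour")
    hu <- if (is.null(el$hu)) spec$hu_bone else el$hu
    a[m] <- hu
    bone_any <- bone_any | m
  }
  vol <- volume_image(a, spec$spacing, origin)

  lm <- .default_landmarks()
  inside <- (lm[, 1] / spec$body_axes[1])^2 + (lm[, 2] / spec$body_axes[2])^2 +
    (lm[, 3] / spec$body_axes[3])^2 <= 1
  lm <- lm[inside, , drop = FALSE]
  truth <- list(applied_transform = six_dof(),
                landmark_positions = lm,
                ptv_center = c(0, -5, 5),
                body_mask = body)
  list(volume = vol, truth = truth)
}

#' Analytic total bone volume of a phantom spec
#' @param spec a [phantom_spec()]
#' @return mm^3 (primitives are disjoint by construction of the default set)
#' @export
phantom_bone_volume <- function(spec) {
  sum(vapply(spec$bone_elements, bone_element_volume, numeric(1)))
}
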