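#' Synthetic-CT surrogate of a phantom CT
#'
#' Emulates the qualitative appearance of a CNN-generated synthetic CT
#' relative to the true CT — blurred edges and decreased contrast of part of
#' the bone structures — by (1) scaling bone voxels toward soft tissue,
#' (2) Gaussian-blurring the volume and (3) adding Gaussian HU noise. The
#' output shares the input grid. With `blur_sigma_mm = 0`,
#' `bone_contrast_scale = 1` and `noise_sd_hu = 0` the input is returned
#' unchanged.
#'
#' @param ct a [volume_image()] in HU
#' @param blur_sigma_mm Gaussian blur standard deviation in mm (>= 0)
#' @param bone_contrast_scale factor in (0, 1]; bone HU above `hu_soft`
#'   becomes `hu_soft + scale * (HU - hu_soft)`
#' @param noise_sd_hu standard deviation of additive Gaussian noise (HU)
#' @param seed integer seed for the noise draw
#' @param hu_soft soft-tissue HU toward which bone contrast is scaled
#' @param hu_bone_lo lowest HU treated as bone for contrast scaling
#' @return a [volume_image()] on the same grid
#' @export
make_sct_surrogate <- function(ct, blur_sigma_mm = 1.5,
                               bone_contrast_scale = 0.8,
                               noise_sd_hu = 20, seed = 1L,
                               hu_soft = 40, hu_bone_lo = 200) {
  if (!inherits(ct, "volume_image")) stop("`ct` must be a volume_image")
  if (!is.finite(blur_sigma_mm) || blur_sigma_mm < 0)
    stop("`blur_sigma_mm` must be >= 0")
  if (!is.finite(bone_contrast_scale) || bone_contrast_scale <= 0 ||
      bone_contrast_scale > 1)
    stop("`bone_contrast_scale` must lie in (0, 1]")
  if (!is.finite(noise_sd_hu) || noise_sd_hu < 0)
    stop("`noise_sd_hu` must be >= 0")
  a <- ct$data
  bone <- a >= hu_bone_lo
  a[bone] <- hu_soft + bone_contrast_scale * (a[bone] - hu_soft)
  out <- volume_image(a, ct$spacing, ct$origin)
  if (blur_sigma_mm > 0) out <- blur_volume(out, blur_sigma_mm)
  if (noise_sd_hu > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              rnorm(length(out$data), 0, noise_sd_hu))
    out$data <- out$data + array(noise, dim(out$data))
  }
  out
}
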