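#' Simulate paired CT- and sCT-based registration result tables
#'
#' Emulates a cohort of setup-verification registrations performed twice per
#' case (and observer): once against the CT reference and once against the
#' sCT reference. The CT-based result represents the daily setup correction
#' (drawn from a zero-mean Gaussian with `base_sd`); the sCT-based result is
#' the CT result plus a per-direction Gaussian difference with the requested
#' mean and SD — so the sCT-minus-CT differences downstream recover exactly
#' the requested moments.
#'
#' @param n_cases number of cases (>= 1)
#' @param n_observers observers per case (>= 1)
#' @param per_direction_mean numeric(6) mean difference per direction
#'   (tx, ty, tz in mm; pitch, yaw, roll in degrees)
#' @param per_direction_sd numeric(6) SD of the differences (>= 0)
#' @param seed integer seed; tables are bit-reproducible per seed
#' @param modality `"3d"` (CBCT-style, 6 DoF) or `"2d"`
#'   (orthogonal-projection-style; roll is not available and is recorded as
#'   `NA` for both references)
#' @param base_sd numeric(6) SD of the underlying CT-based couch correction
#' @return data.frame with columns `case`, `observer`, `modality`,
#'   `reference` (`"ct"`/`"sct"`), `tx`, `ty`, `tz`, `pitch`, `yaw`, `roll`
#' @export
sample_paired_registrations <- function(n_cases, n_observers = 1L,
                                        per_direction_mean = rep(0, 6),
                                        per_direction_sd = rep(0.5, 6),
                                        seed = 1L, modality = c("3d", "2d"),
                                        base_sd = c(2, 2, 2, 1, 1, 1)) {
  modality <- match.arg(modality)
  if (n_cases < 1L || n_observers < 1L)
    stop("`n_cases` and `n_observers` must be >= 1")
  if (length(per_direction_mean) != 6L || length(per_direction_sd) != 6L)
    stop("per-direction mean and sd must have length 6")
  if (any(per_direction_sd < 0)) stop("`per_direction_sd` must be >= 0")
  n <- n_cases * n_observers
  dof <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  withr::with_seed(as.integer(seed), {
    ct <- sapply(seq_len(6), function(k) rnorm(n, 0, base_sd[k]))
    diff <- sapply(seq_len(6), function(k)
      rnorm(n, per_direction_mean[k], per_direction_sd[k]))
  })
  ct <- matrix(ct, nrow = n); diff <- matrix(diff, nrow = n)
  sct <- ct + diff
  if (modality == "2d") ct[, 6] <- sct[, 6] <- NA_real_
  idx <- data.frame(case = rep(seq_len(n_cases), each = n_observers),
                    observer = rep(seq_len(n_observers), times = n_cases))
  tab <- rbind(
    cbind(idx, modality = modality, reference = "ct",
          as.data.frame(`colnames<-`(ct, dof))),
    cbind(idx, modality = modality, reference = "sct",
          as.data.frame(`colnames<-`(sct, dof))))
  tab <- tab[order(tab$case, tab$observer, tab$reference), ]
  rownames(tab) <- NULL
  tab
}

#' Jittered repeat placements of ground-truth landmarks
#'
#' Emulates an operator repeatedly placing anatomical landmarks: each repeat
#' is the true landmark set plus isotropic Gaussian jitter of the given SD.
#'
#' @param truth the `truth` element of [make_phantom()] output (or any list
#'   with a labelled `landmark_positions` matrix)
#' @param jitter_sd_mm isotropic placement jitter SD in mm (>= 0)
#' @param n_repeats number of placements (>= 1)
#' @param seed integer seed
#' @return list of `n_repeats` labelled n x 3 matrices (mm)
#' @export
place_landmarks <- function(truth, jitter_sd_mm = 1, n_repeats = 10L,
                            seed = 1L) {
  lm <- truth$landmark_positions
  if (is.null(lm) || !is.matrix(lm)) stop("truth must carry landmark_positions")
  if (!is.finite(jitter_sd_mm) || jitter_sd_mm < 0)
    stop("`jitter_sd_mm` must be >= 0")
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1")
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_repeats), function(r) {
      lm + matrix(rnorm(length(lm), 0, jitter_sd_mm), nrow = nrow(lm))
    })
  })
}
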