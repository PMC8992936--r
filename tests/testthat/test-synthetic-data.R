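test_that("phantom contains exactly the air/soft/bone HU levels with a consistent body mask", {
  ph <- small_phantom()
  spec <- small_spec()
  expect_setequal(unique(as.vector(ph$volume$data)),
                  c(spec$hu_air, spec$hu_soft, spec$hu_bone))
  expect_identical(ph$truth$body_mask, ph$volume$data > spec$hu_air)
  # landmarks inside the body
  lm <- ph$truth$landmark_positions
  expect_gt(nrow(lm), 3)
  inside <- (lm[, 1] / spec$body_axes[1])^2 + (lm[, 2] / spec$body_axes[2])^2 +
    (lm[, 3] / spec$body_axes[3])^2 <= 1
  expect_true(all(inside))
  # >= 3 distinct bone element kinds present
  kinds <- vapply(spec$bone_elements, function(e) e$type, character(1))
  expect_true(all(c("shell", "cylinder", "arc") %in% kinds))
})

test_that("phantom generation is deterministic and validates its spec", {
  a <- make_phantom(small_spec())
  b <- make_phantom(small_spec())
  expect_identical(a$volume$data, b$volume$data)
  expect_error(phantom_spec(spacing = c(0, 1, 1)), "positive")
  expect_error(phantom_spec(grid_shape = c(8, 32, 32)), ">= 16")
  expect_error(phantom_spec(hu_bone = 1900), "1700")
  expect_error(phantom_spec(hu_soft = -2000), "ordering")
  # a bone element poking outside the body is rejected at rasterization
  bad <- phantom_spec(bone_elements = list(
    list(type = "cylinder", center = c(0, 44, 0), radius = 8, height = 14)))
  expect_error(make_phantom(bad), "outside the body")
})

test_that("voxelized bone fraction matches the closed-form solid volumes", {
  spec <- phantom_spec() # full-resolution default
  ph <- make_phantom(spec)
  frac <- mean(ph$volume$data >= 200 & ph$volume$data <= 1700)
  analytic <- phantom_bone_volume(spec) /
    prod(dim(ph$volume$data) * ph$volume$spacing)
  expect_lt(abs(frac - analytic) / analytic, 0.02)
})

test_that("sCT surrogate: identity settings, contrast formula, determinism", {
  ct <- small_phantom()$volume
  ident <- make_sct_surrogate(ct, blur_sigma_mm = 0, bone_contrast_scale = 1,
                              noise_sd_hu = 0)
  expect_equal(ident$data, ct$data)
  scaled <- make_sct_surrogate(ct, blur_sigma_mm = 0,
                               bone_contrast_scale = 0.8, noise_sd_hu = 0)
  expect_equal(max(scaled$data), 40 + 0.8 * (900 - 40))
  s1 <- make_sct_surrogate(ct, 1, 0.8, 15, seed = 42)
  s2 <- make_sct_surrogate(ct, 1, 0.8, 15, seed = 42)
  expect_identical(s1$data, s2$data)
  expect_error(make_sct_surrogate(ct, bone_contrast_scale = 0), "0, 1")
  expect_error(make_sct_surrogate(ct, bone_contrast_scale = 1.2), "0, 1")
  expect_error(make_sct_surrogate(ct, blur_sigma_mm = -1), ">= 0")
})

test_that("deformation kinds carry correct analytic Jacobian metadata", {
  g <- list(dim = c(20, 20, 20), spacing = c(3, 3, 3), origin = rep(-28.5, 3))
  idf <- make_deformation(g, "identity")
  expect_true(all(idf$u == 0))
  expect_equal(idf$jd_analytic(matrix(0, 1, 3)), 1)
  aff <- make_deformation(g, "affine_scale",
                          params = list(scale = c(1.1, 1.0, 0.9)))
  expect_equal(unique(aff$jd_analytic(matrix(rnorm(30), 10, 3))), 0.99)
  fold <- make_deformation(g, "folding", params = list(sigma_mm = 10))
  expect_lt(fold$jd_min_analytic, 0)
  # the analytic minimum sits at one sigma above centre on the bump axis
  zmin <- fold$jd_analytic(matrix(c(0, 0, 10), 1, 3))
  expect_equal(zmin, fold$jd_min_analytic, tolerance = 1e-12)
  expect_error(make_deformation(g, "vortex"), "arg")
})

test_that("PTV generator: counts, radii, determinism, validation", {
  s <- make_ptv(center = c(0, 0, 0), semi_axes = c(20, 20, 20),
                n_slices = 10, pts_per_contour = 64)
  pts <- structure_points(s)
  expect_identical(nrow(pts), 640L)
  expect_true(all(sqrt(rowSums(pts^2)) <= 20 + 1e-9))
  s2 <- make_ptv(center = c(0, 0, 0), semi_axes = c(20, 20, 20),
                 n_slices = 10, pts_per_contour = 64)
  expect_identical(structure_points(s2), pts)
  expect_error(make_ptv(semi_axes = c(20, 0, 20)), "> 0")
  expect_error(make_ptv(n_slices = 1), ">= 2")
  expect_error(make_ptv(pts_per_contour = 4), ">= 8")
})

test_that("paired registration tables reproduce requested difference moments", {
  exact <- sample_paired_registrations(5, 2, rep(0, 6), rep(0, 6), seed = 3)
  ct <- exact[exact$reference == "ct", c("tx", "ty", "tz", "pitch", "yaw", "roll")]
  sct <- exact[exact$reference == "sct", c("tx", "ty", "tz", "pitch", "yaw", "roll")]
  expect_equal(as.matrix(ct), as.matrix(sct), ignore_attr = TRUE)

  mu <- c(0.4, -0.2, 0.1, 0.3, 0, -0.1)
  sd6 <- c(0.7, 0.5, 0.6, 0.4, 0.3, 0.4)
  big <- sample_paired_registrations(10000, 1, mu, sd6, seed = 11)
  d <- dof_differences(big)
  for (k in seq_along(levels(d$direction))) {
    v <- d$difference[as.integer(d$direction) == k]
    expect_lt(abs(mean(v) - mu[k]), 3 * sd6[k] / sqrt(10000) + 1e-12)
  }
  again <- sample_paired_registrations(10000, 1, mu, sd6, seed = 11)
  expect_identical(big, again)
  # 2D tables have no roll
  t2 <- sample_paired_registrations(3, 2, modality = "2d", seed = 1)
  expect_true(all(is.na(t2$roll)))
})

test_that("landmark placement jitter has the 3D Gaussian radial mean", {
  ph <- small_phantom()
  same <- place_landmarks(ph$truth, jitter_sd_mm = 0, n_repeats = 3, seed = 1)
  expect_equal(same[[1]], ph$truth$landmark_positions)
  expect_equal(same[[3]], ph$truth$landmark_positions)
  expect_length(place_landmarks(ph$truth, 1, n_repeats = 10, seed = 1), 10)
  reps <- place_landmarks(ph$truth, jitter_sd_mm = 1, n_repeats = 10000,
                          seed = 5)
  dev <- vapply(reps, function(r)
    mean(sqrt(rowSums((r - ph$truth$landmark_positions)^2))), numeric(1))
  expected <- 2 * sqrt(2 / pi)  # E|N3(0, I)| = sigma * 2 * sqrt(2/pi)
  expect_lt(abs(mean(dev) - expected) / expected, 0.02)
  expect_error(place_landmarks(ph$truth, -1), ">= 0")
})
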