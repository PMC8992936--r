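test_that("bone mask matches the phantom's bone voxels and honours the VOI", {
  ph <- small_phantom()
  cfg <- registration_config()
  m <- bone_mask(ph$volume, cfg)
  expect_identical(m, ph$volume$data == 900)
  soft <- volume_image(array(40, c(16, 16, 16)))
  expect_error(bone_mask(soft, cfg), "200.*1700")
  # VOI covering z >= 0 only: restricted count equals direct count
  voi <- c(-200, -200, 0, 200, 200, 200)
  mv <- bone_mask(ph$volume, registration_config(voi = voi))
  pts <- voxel_coordinates(ph$volume, which = which(m))
  expect_identical(sum(mv), sum(pts[, 3] >= 0))
})

test_that("mutual information: self-entropy, symmetry, independence bias", {
  ph <- small_phantom()
  v <- ph$volume$data
  miself <- mutual_information(v, v, n_bins = 32)
  p <- tabulate(pmin(32, 1 + floor((v - min(v)) / diff(range(v)) * 32)),
                nbins = 32) / length(v)
  expect_equal(miself, -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
  set.seed(9)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_equal(mutual_information(a, b, n_bins = 16),
               mutual_information(b, a, n_bins = 16), tolerance = 1e-12)
  expect_gte(mutual_information(a, b, n_bins = 16), 0)
  # independent uniforms: MI below the n_bins^2 / (2 n) bias bound
  n <- 1e6; nb <- 8
  u1 <- runif(n); u2 <- runif(n)
  expect_lt(mutual_information(u1, u2, n_bins = nb), nb^2 / (2 * n))
  expect_warning(mutual_information(rep(1, 100), rnorm(100)), "constant")
})

test_that("DRR projection: uniformity, shift commutation, column position", {
  u <- volume_image(array(100, c(12, 12, 12)))
  pf <- project_drr(u, "frontal")
  expect_equal(diff(range(pf$data)), 0)
  ph <- small_phantom()
  vol <- ph$volume
  # integer-voxel in-plane shift commutes with projection
  sh <- vol
  sh$data <- array(-1000, dim(vol$data))
  sh$data[3:dim(vol$data)[1], , ] <-
    vol$data[1:(dim(vol$data)[1] - 2), , ]
  p0 <- project_drr(vol, "frontal")$data
  p1 <- project_drr(sh, "frontal")$data
  expect_equal(p1[3:nrow(p1), ], p0[1:(nrow(p0) - 2), ], tolerance = 1e-12)
  # the vertebral column shows as elevated intensity at x ~ 0
  spec <- small_spec()
  col_x <- which.max(rowSums(project_drr(vol, "frontal")$data))
  xs <- vol$origin[1] + (seq_len(dim(vol$data)[1]) - 1) * vol$spacing[1]
  expect_lt(abs(xs[col_x]), 2 * vol$spacing[1])
})

test_that("registering a volume to itself returns near-zero parameters, deterministically", {
  ph <- small_phantom()
  cfg <- registration_config(max_iter = 200)
  r1 <- register_rigid_3d(ph$volume, ph$volume, cfg)
  p <- as.numeric(r1$params)
  expect_true(all(abs(p[1:3]) <= 0.1))
  expect_true(all(abs(p[4:6]) <= 0.1))
  expect_gte(r1$final_metric, 0)
  r2 <- register_rigid_3d(ph$volume, ph$volume, cfg)
  expect_identical(as.numeric(r1$params), as.numeric(r2$params))
  expect_identical(r1$final_metric, r2$final_metric)
})

test_that("known offsets are recovered on a coarse phantom", {
  ph <- make_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                  spacing = c(2.3, 2.3, 4.0)))
  applied <- six_dof(2, -1.5, 2, 1, 0, -1)
  moved <- transform_volume(ph$volume, applied)
  r <- register_rigid_3d(moved, ph$volume, registration_config())
  expect_lt(max(abs(as.numeric(r$params)[1:3] - as.numeric(applied)[1:3])),
            0.5 * max(ph$volume$spacing))
  expect_lt(max(abs(as.numeric(r$params)[4:6] - as.numeric(applied)[4:6])),
            0.5)
  # MI at the recovered optimum beats MI of the unregistered pose
  mask <- bone_mask(ph$volume, registration_config())
  expect_gt(r$final_metric, 0)
})

test_that("2D positioning recovers translations with roll frozen at zero", {
  ph <- make_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                  spacing = c(3.4, 3.4, 6.0)))
  off <- six_dof(1.5, -1.0, 2.0)
  treat <- transform_volume(ph$volume, off)
  projs <- list(project_drr(treat, "frontal"), project_drr(treat, "lateral"))
  r <- register_rigid_2d(ph$volume, projs, registration_config(max_iter = 250))
  expect_identical(as.numeric(r$params)[6], 0)
  expect_lt(max(abs(as.numeric(r$params)[1:3] - as.numeric(off)[1:3])),
            0.5 * max(ph$volume$spacing))
  expect_error(register_rigid_2d(ph$volume, list(projs[[1]], projs[[1]])),
               "frontal and.*lateral")
})

test_that("sCT degradation degrades but does not break recovery", {
  ph <- make_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                  spacing = c(2.3, 2.3, 4.0)))
  applied <- six_dof(1.5, 1.5, -2, 0.8, -0.8, 0.5)
  moved <- transform_volume(ph$volume, applied)
  err_for <- function(ref) {
    r <- register_rigid_3d(moved, ref, registration_config())
    max(abs(as.numeric(r$params)[1:3] - as.numeric(applied)[1:3]))
  }
  e_exact <- err_for(ph$volume)
  e_mild <- err_for(make_sct_surrogate(ph$volume, 0.8, 0.9, 0, seed = 2))
  e_strong <- err_for(make_sct_surrogate(ph$volume, 2.0, 0.7, 0, seed = 2))
  expect_lt(e_exact, 0.5 * max(ph$volume$spacing))
  expect_lt(e_mild, 1.0 * max(ph$volume$spacing))
  expect_lt(e_strong, 1.5 * max(ph$volume$spacing))
})
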