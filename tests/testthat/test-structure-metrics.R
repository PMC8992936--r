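test_that("paired PTV distances: spike at zero, spike at |t|, rotation chord lengths", {
  ptv <- make_ptv(center = c(0, 0, 0), semi_axes = c(20, 25, 30),
                  n_slices = 8, pts_per_contour = 32)
  m0 <- build_matrix(six_dof())
  same <- paired_ptv_distances(ptv, m0, m0)
  expect_true(all(same$per_point_distances == 0))
  expect_identical(sum(same$histogram$counts), 256L)
  expect_equal(same$histogram$counts[1], 256L) # spike in the first bin

  mt <- build_matrix(six_dof(1, 2, 2))
  tr <- paired_ptv_distances(ptv, mt, m0)
  expect_equal(tr$per_point_distances, rep(3, 256), tolerance = 1e-12)
  expect_equal(tr$mean, 3)
  expect_equal(tr$max, 3)
  # the histogram is a single spike, in the bin containing 3 mm
  spike_bin <- which(tr$histogram$counts > 0)
  expect_length(spike_bin, 1)
  expect_identical(tr$histogram$counts[spike_bin], 256L)
  expect_lte(tr$histogram$breaks[spike_bin], 3)
  expect_gte(tr$histogram$breaks[spike_bin + 1], 3)

  # pure rotation delta about centre c: distance = 2 r sin(delta/2) with r
  # the distance of the point from the rotation axis (brute force per point)
  delta <- 2.5
  ctr <- c(5, -5, 0)
  mr <- build_matrix(six_dof(roll = delta), center = ctr)
  rot <- paired_ptv_distances(ptv, mr, m0)
  pts <- structure_points(ptv)
  r_axis <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  expect_equal(rot$per_point_distances,
               2 * r_axis * sin(delta * pi / 360), tolerance = 1e-9)
  expect_error(paired_ptv_distances(structure_set(list()), m0, m0))
})

test_that("paired distances are invariant under a common extra rigid transform", {
  ptv <- make_ptv(center = c(0, -5, 5), semi_axes = c(18, 22, 28),
                  n_slices = 10, pts_per_contour = 48)
  ma <- build_matrix(six_dof(0.5, -1, 2, 1, 0.5, -0.8))
  mb <- build_matrix(six_dof(-0.3, 0.7, 1.2, -0.4, 1.1, 0.2))
  extra <- build_matrix(six_dof(3, -2, 4, 2, -1, 1.5), center = c(10, 0, -5))
  base <- paired_ptv_distances(ptv, ma, mb)
  comp <- paired_ptv_distances(ptv, compose_matrices(extra, ma),
                               compose_matrices(extra, mb))
  expect_equal(comp$per_point_distances, base$per_point_distances,
               tolerance = 1e-9)
  # max distance occurs at the point farthest from the relative rotation
  # axis -- cross-check against explicit per-point maximization
  expect_equal(base$max, max(base$per_point_distances))
})

test_that("rasterization reproduces the analytic ellipsoid volume and shifts exactly", {
  s <- make_ptv(center = c(0, 0, 0), semi_axes = c(20, 20, 20),
                n_slices = 10, pts_per_contour = 64)
  r <- rasterize_structure(s, grid_spacing_mm = 1)
  analytic <- 4 / 3 * pi * 20^3
  expect_lt(abs(sum(r$data) - analytic) / analytic, 0.05)
  # integer-grid-step translation shifts the mask by exactly one voxel
  s2 <- transform_structure(s, build_matrix(six_dof(tx = 1)))
  s2 <- structure_set(s2$contours)
  r2 <- rasterize_structure(s2, grid_spacing_mm = 1)
  expect_equal(sum(r2$data), sum(r$data))
  expect_error(rasterize_structure(structure_set(list())), "non-empty")
  bowtie <- list(cbind(c(0, 2, 0, 2), c(0, 2, 2, 0), c(0, 0, 0, 0)))
  expect_error(rasterize_structure(structure_set(bowtie)),
               "self-intersecting")
})

test_that("Dice coefficient: identical, disjoint, half-overlap, symmetry, monotone decay", {
  a <- array(0, c(20, 20, 20)); a[2:11, 2:11, 2:11] <- 1
  expect_equal(dice(a, a)$dsc, 1)
  b <- array(0, c(20, 20, 20)); b[12:19, 12:19, 12:19] <- 1
  expect_equal(dice(a, b)$dsc, 0)
  # two 10-voxel cubes overlapping in half their volume
  h <- array(0, c(20, 20, 20)); h[7:16, 2:11, 2:11] <- 1
  ov <- dice(a, h)
  expect_equal(ov$dsc, 0.5)
  expect_identical(ov$voxel_counts[["intersection"]], 500L)
  expect_equal(dice(h, a)$dsc, dice(a, h)$dsc)
  dscs <- sapply(0:6, function(sh) {
    s <- array(0, c(20, 20, 20)); s[(2 + sh):(11 + sh), 2:11, 2:11] <- 1
    dice(a, s)$dsc
  })
  expect_true(all(diff(dscs) <= 0))
  expect_error(dice(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))), "empty")
})

test_that("observer summary pools per-observer means and flags the worst observer", {
  mkrep <- function(d) structure(
    list(per_point_distances = d, mean = mean(d), sd = sd(d), max = max(d)),
    class = "distance_report")
  one <- observer_summary(list(a = mkrep(c(1, 2, 3))))
  expect_equal(one$mean_of_means, 2)
  expect_equal(one$sd_of_means, 0)
  flat <- observer_summary(list(a = mkrep(rep(2.5, 10)),
                                b = mkrep(rep(2.5, 4))))
  expect_equal(flat$mean_of_means, 2.5)
  expect_equal(flat$max_distance, 2.5)
  set.seed(22)
  reps <- lapply(1:6, function(i) mkrep(rnorm(50, mean = i / 2, sd = 0.2)))
  names(reps) <- paste0("obs", 1:6)
  s <- observer_summary(reps)
  means <- sapply(reps, function(r) r$mean)
  expect_equal(s$mean_of_means, mean(means))
  expect_equal(s$sd_of_means, sd(means))
  expect_identical(s$worst_observer, names(which.max(means)))
  expect_equal(s$worst_mean, max(means))
  expect_equal(s$max_distance, max(sapply(reps, function(r) r$max)))
})

test_that("registered-PTV Dice falls with relative transform magnitude", {
  ptv <- make_ptv(center = c(0, 0, 0), semi_axes = c(18, 18, 24),
                  n_slices = 10, pts_per_contour = 32)
  m0 <- build_matrix(six_dof())
  near <- registered_ptv_dice(ptv, build_matrix(six_dof(0.5, 0, 0)), m0,
                              grid_spacing_mm = 2)
  far <- registered_ptv_dice(ptv, build_matrix(six_dof(8, 0, 0)), m0,
                             grid_spacing_mm = 2)
  expect_gt(near$dsc, 0.9)
  expect_gt(near$dsc, far$dsc)
  proj <- registered_ptv_dice(ptv, build_matrix(six_dof(0.5, 0, 0)), m0,
                              grid_spacing_mm = 2, projected = TRUE)
  expect_gt(proj$dsc, 0.9)
})
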