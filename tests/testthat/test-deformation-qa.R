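test_that("Jacobian determinant: identity, affine scale, folding detection", {
  g <- list(dim = c(24, 24, 24), spacing = c(3, 3, 4),
            origin = -c(23, 23, 23) * c(3, 3, 4) / 2)
  idr <- jacobian_determinant(make_deformation(g, "identity"))
  expect_true(all(idr$jd_field == 1))
  expect_true(idr$realistic)
  aff <- jacobian_determinant(
    make_deformation(g, "affine_scale", params = list(scale = c(1.1, 1, 0.9))))
  expect_lt(max(abs(aff$jd_field - 0.99)), 1e-6)
  expect_true(aff$realistic)
  fold <- make_deformation(g, "folding", params = list(sigma_mm = 12))
  fr <- jacobian_determinant(fold)
  expect_gt(fr$fraction_nonpositive, 0)
  expect_false(fr$realistic)
  expect_lt(fr$min_jd, 0)
  expect_error(jacobian_determinant(make_deformation(g, "identity"),
                                    mask = array(FALSE, g$dim)), "empty")
})

test_that("finite-difference JD converges to the analytic JD at O(h^2)", {
  errs <- sapply(c(4, 2), function(h) {
    n <- as.integer(120 / h)
    g <- list(dim = rep(n, 3), spacing = rep(h, 3),
              origin = rep(-(n - 1) * h / 2, 3))
    f <- make_deformation(g, "gaussian_bump",
                          params = list(sigma_mm = 15, amplitude_mm = 4))
    jd <- jacobian_determinant(f)
    pts <- posequiv:::.grid_points(g$dim, g$spacing, g$origin)
    ana <- array(f$jd_analytic(pts), g$dim)
    i <- 3:(n - 2)
    max(abs(jd$jd_field[i, i, i] - ana[i, i, i]))
  })
  expect_gt(errs[1] / errs[2], 3) # halving h divides the error by ~4
})

test_that("one-sided differencing at the mask border avoids spurious JD", {
  g <- list(dim = c(20, 20, 20), spacing = c(3, 3, 3), origin = rep(-28.5, 3))
  f <- make_deformation(g, "affine_scale", params = list(scale = c(1.05, 1, 1)))
  pts <- posequiv:::.grid_points(g$dim, g$spacing, g$origin)
  ball <- array(rowSums(pts^2) <= 20^2, g$dim)
  r <- jacobian_determinant(f, mask = ball)
  expect_lt(max(abs(r$jd_field[ball] - 1.05)), 1e-9)
  expect_true(all(is.na(r$jd_field[!ball])))
})

test_that("landmark offsets respond only through the definitions that use a moved landmark", {
  ph <- small_phantom()
  lm <- ph$truth$landmark_positions
  same <- landmark_offsets(lm, lm)
  expect_true(all(same$difference == 0))
  moved <- lm
  moved["spinal_canal_c2", 3] <- moved["spinal_canal_c2", 3] + 2
  r <- landmark_offsets(lm, moved)
  # c2 - c4 IS distance in image B grows by 2, so difference A - B is -2
  expect_equal(r$difference[r$name == "c2_canal_to_c4_canal_IS"], -2)
  untouched <- !grepl("c2", r$name)
  expect_true(all(r$difference[untouched] == 0))
  bad <- lm; rownames(bad)[1] <- "elsewhere"
  expect_error(landmark_offsets(lm, bad), "label")
})

test_that("offset SD across jittered cases propagates as sigma * sqrt(2) per axis", {
  ph <- small_phantom()
  sigma <- 1
  defs <- list(list(name = "c2c4", labels = c("spinal_canal_c2",
                                              "spinal_canal_c4"),
                    axis = "IS"))
  set.seed(77)
  diffs <- replicate(10000, {
    a <- ph$truth$landmark_positions +
      matrix(rnorm(length(ph$truth$landmark_positions), 0, sigma),
             nrow = nrow(ph$truth$landmark_positions))
    b <- ph$truth$landmark_positions +
      matrix(rnorm(length(ph$truth$landmark_positions), 0, sigma),
             nrow = nrow(ph$truth$landmark_positions))
    (a["spinal_canal_c2", 3] - a["spinal_canal_c4", 3]) -
      (b["spinal_canal_c2", 3] - b["spinal_canal_c4", 3])
  })
  # each within-image axis distance has SD sigma*sqrt(2); the between-image
  # difference doubles the variance again -> 2 sigma
  expect_lt(abs(sd(diffs) - 2 * sigma) / (2 * sigma), 0.03)
})

test_that("euclidean-axis offsets are invariant under a common rigid transform", {
  ph <- small_phantom()
  lm <- ph$truth$landmark_positions
  jit <- lm + matrix(rnorm(length(lm), 0, 1), nrow = nrow(lm))
  defs <- list(list(name = "cm", labels = c("mandibular_condyle_left",
                                            "mastoid_left"),
                    axis = "euclidean"))
  base <- landmark_offsets(lm, jit, defs)
  m <- build_matrix(six_dof(4, -3, 2, 5, -4, 3), center = c(10, 0, 0))
  rot_a <- apply_to_points(m, lm); rownames(rot_a) <- rownames(lm)
  rot_b <- apply_to_points(m, jit); rownames(rot_b) <- rownames(lm)
  moved <- landmark_offsets(rot_a, rot_b, defs)
  expect_equal(moved$difference, base$difference, tolerance = 1e-9)
})

test_that("landmark reproducibility statistics match their closed forms", {
  expect_equal(landmark_reproducibility(matrix(1, 4, 3)),
               list(mean_mm = 0, max_mm = 0))
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(landmark_reproducibility(two), list(mean_mm = 1, max_mm = 1))
  expect_error(landmark_reproducibility(matrix(0, 1, 3)), "at least 2")
  set.seed(88)
  reps <- matrix(rnorm(3 * 10000, 0, 1), ncol = 3)
  r <- landmark_reproducibility(reps)
  maxwell_mean <- 2 * sqrt(2 / pi)
  expect_lt(abs(r$mean_mm - maxwell_mean) / maxwell_mean, 0.02)
  rp <- landmark_reproducibility(reps[1:100, ], statistic = "pairwise")
  expect_gt(rp$mean_mm, r$mean_mm) # pairwise distances are sqrt(2) larger
})
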