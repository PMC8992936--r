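test_that("dof_differences subtracts CT from sCT with sign preserved", {
  tab <- sample_paired_registrations(3, 1, rep(0, 6), rep(0, 6), seed = 1)
  d <- dof_differences(tab)
  expect_true(all(d$difference == 0))
  # hand-built single pair: sCT (1,0,...) vs CT (0,...): RL difference +1
  one <- data.frame(case = 1, observer = 1, modality = "3d",
                    reference = c("ct", "sct"),
                    tx = c(0, 1), ty = 0, tz = 0,
                    pitch = 0, yaw = 0, roll = 0)
  d1 <- dof_differences(one)
  expect_equal(d1$difference[d1$direction == "RL"], 1)
  expect_true(all(d1$difference[d1$direction != "RL"] == 0))
  broken <- one[one$reference == "ct", ]
  expect_error(dof_differences(broken), "case 1")
})

test_that("summarize_differences reports mean, n-1 SD, min, max", {
  tab <- data.frame(case = 1:3, observer = 1, modality = "3d",
                    direction = factor("RL"), difference = c(1, 2, 3))
  s <- summarize_differences(tab)
  expect_equal(s$mean, 2); expect_equal(s$sd, 1)
  expect_equal(s$min, 1); expect_equal(s$max, 3)
  single <- tab[1, ]
  s1 <- summarize_differences(single)
  expect_equal(s1$mean, 1)
  expect_true(is.na(s1$sd))
  empty <- data.frame(case = 1, observer = 1, modality = "2d",
                      direction = factor("roll"), difference = NA_real_)
  expect_warning(summarize_differences(empty), "omitted")
  big <- sample_paired_registrations(10000, 1, c(0.4, rep(0, 5)),
                                     c(0.7, rep(0.1, 5)), seed = 4)
  sb <- summarize_differences(dof_differences(big))
  rl <- sb[sb$direction == "RL", ]
  expect_lt(abs(rl$mean - 0.4), 3 * 0.7 / sqrt(10000))
  expect_lt(abs(rl$sd - 0.7), 0.02)
})

test_that("TOST p-values match the shifted one-sided t.test oracle to 1e-8", {
  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(sample(5:40, 1), runif(1, -1.5, 1.5), runif(1, 0.1, 2))
    got <- tost_paired(x)
    expect_lt(abs(got$p_lower -
                    t.test(x, mu = -1, alternative = "greater")$p.value), 1e-8)
    expect_lt(abs(got$p_upper -
                    t.test(x, mu = 1, alternative = "less")$p.value), 1e-8)
    expect_identical(got$p_overall, max(got$p_lower, got$p_upper))
    expect_identical(got$equivalent, got$p_overall < 0.05)
  }
})

test_that("TOST decisions: clear equivalence, clear non-equivalence, boundary", {
  set.seed(14)
  tight <- rnorm(14, 0, 0.3)
  r <- tost_paired(tight)
  expect_true(r$equivalent)
  expect_lt(r$p_overall, 0.001)
  off <- rnorm(14, 1.5, 0.4)
  r2 <- tost_paired(off)
  expect_false(r2$equivalent)
  expect_gt(r2$p_upper, 0.5)
  # mean pinned at the upper bound, large n: p_upper ~ 0.5
  at_bound <- rnorm(4000, 0, 0.5)
  at_bound <- at_bound - mean(at_bound) + 1 # mean exactly 1
  r3 <- tost_paired(at_bound)
  expect_equal(r3$p_upper, 0.5, tolerance = 0.01)
  expect_false(r3$equivalent)
  expect_warning(r0 <- tost_paired(rep(0.2, 10)), "degenerate")
  expect_true(r0$equivalent)
  expect_error(tost_paired(c(1)), "at least 2")
  expect_error(tost_paired(rnorm(5), low = 1, high = -1), "low")
})

test_that("equivalence report pools translations per modality and localizes failures", {
  null3 <- sample_paired_registrations(14, 1, rep(0, 6), rep(0.3, 6),
                                       seed = 8, modality = "3d")
  null2 <- sample_paired_registrations(14, 6, rep(0, 6), c(rep(0.3, 5), 0),
                                       seed = 9, modality = "2d")
  rep0 <- equivalence_report(dof_differences(rbind(null3, null2)))
  expect_true(rep0[["3d"]]$pooled$equivalent)
  expect_true(rep0[["2d"]]$pooled$equivalent)
  expect_identical(rep0[["3d"]]$pooled$n, 42L) # 14 cases x 3 axes

  shifted <- sample_paired_registrations(
    20, 1, c(0, 2, 0, 0, 0, 0), rep(0.3, 6), seed = 10, modality = "3d")
  repS <- equivalence_report(dof_differences(shifted))
  expect_false(repS[["3d"]]$per_direction$PA$equivalent)
  expect_true(repS[["3d"]]$per_direction$RL$equivalent)
  expect_true(repS[["3d"]]$per_direction$IS$equivalent)

  # the study's measured moments at its cohort size: pooled 3D equivalence
  t2 <- sample_paired_registrations(
    14, 1, c(0.1, 0.4, -0.7, 0.3, 0.0, 0.0), c(0.5, 0.7, 0.6, 0.5, 0.3, 0.4),
    seed = 12, modality = "3d")
  repT <- equivalence_report(dof_differences(t2))
  expect_true(repT[["3d"]]$pooled$equivalent)
})
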