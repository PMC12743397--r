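test_that("unpaired t trajectories match the scalar oracle and are
           antisymmetric", {
  set.seed(60)
  a <- matrix(rnorm(8 * 10), 8, 10)
  b <- matrix(rnorm(6 * 10, mean = 0.5), 6, 10)
  t_traj <- t_trajectory_unpaired(a, b)
  for (j in c(1, 5, 10)) {
    expect_equal(t_traj[j],
                 unname(t.test(a[, j], b[, j], var.equal = TRUE)$statistic))
  }
  expect_equal(t_trajectory_unpaired(b, a), -t_traj)

  # hand-computed example: A = {0,0,1,1}, B = {2,2,3,3}
  a2 <- matrix(c(0, 0, 1, 1), 4, 1)
  b2 <- matrix(c(2, 2, 3, 3), 4, 1)
  expect_equal(t_trajectory_unpaired(a2, b2),
               unname(t.test(a2, b2, var.equal = TRUE)$statistic))

  # identical groups -> t = 0 everywhere
  expect_equal(t_trajectory_unpaired(a, a), rep(0, 10))

  # zero pooled variance names the timepoint
  a3 <- a; a3[, 4] <- 1
  b3 <- b; b3[, 4] <- 1
  expect_error(t_trajectory_unpaired(a3, b3), "timepoint.*3")
  expect_error(t_trajectory_unpaired(a[1, , drop = FALSE], b), "at least 2")
})

test_that("paired t trajectories match the scalar oracle and handle
           degenerate cases", {
  set.seed(61)
  pre <- matrix(rnorm(9 * 12), 9, 12)
  post <- pre + matrix(rnorm(9 * 12, mean = 0.3), 9, 12)
  t_traj <- t_trajectory_paired(pre, post)
  for (j in c(2, 7, 12)) {
    expect_equal(t_traj[j],
                 unname(t.test(post[, j], pre[, j], paired = TRUE)$statistic))
  }
  # post = pre -> 0 everywhere (0/0 convention)
  expect_equal(t_trajectory_paired(pre, pre), rep(0, 12))
  # constant shift: zero difference variance with nonzero mean -> error
  expect_error(t_trajectory_paired(pre, pre + 5), "zero difference variance")
  expect_error(t_trajectory_paired(pre, post[1:5, ]), "identical dimensions")
})

test_that("exhaustive enumeration is used for small designs", {
  set.seed(62)
  pre <- matrix(rnorm(4 * 8), 4, 8)
  post <- pre + matrix(rnorm(4 * 8, 0.2), 4, 8)
  crit <- permutation_critical_value(pre, post, "paired", n_perm = 1000)
  expect_equal(attr(crit, "n_permutations"), 16L)
  expect_true(attr(crit, "exhaustive"))

  a <- matrix(rnorm(5 * 8), 5, 8)
  b <- matrix(rnorm(5 * 8), 5, 8)
  crit2 <- permutation_critical_value(a, b, "unpaired", n_perm = 1000)
  expect_equal(attr(crit2, "n_permutations"), choose(10, 5))
  expect_true(attr(crit2, "exhaustive"))

  expect_error(permutation_critical_value(pre[1:3, ], post[1:3, ], "paired"),
               "10 distinct")
  expect_error(permutation_critical_value(a, b, "unpaired", alpha = 0.6),
               "alpha")
})

test_that("permutation thresholds are invariant to unit rescaling", {
  set.seed(63)
  a <- smooth_noise(10, 50)
  b <- smooth_noise(10, 50)
  c1 <- permutation_critical_value(a, b, "unpaired", n_perm = 300, seed = 4)
  c2 <- permutation_critical_value(1000 * a, 1000 * b, "unpaired",
                                   n_perm = 300, seed = 4)
  expect_equal(as.numeric(c1), as.numeric(c2), tolerance = 1e-10)
})

test_that("a strong constant offset is significant across the whole
           trajectory", {
  set.seed(64)
  a <- smooth_noise(10, 101)
  b <- smooth_noise(10, 101) + 5   # 5 within-subject SDs everywhere
  t_traj <- t_trajectory_unpaired(b, a)
  crit <- permutation_critical_value(b, a, "unpaired", n_perm = 500,
                                     seed = 2)
  res <- spm_summarize(t_traj, crit, channel = "x")
  expect_equal(res$significant_fraction, 100)
  expect_equal(nrow(res$regions), 1)
  expect_equal(unname(res$regions[1, ]), c(0, 101))
})

test_that("summarize extracts maximal runs matching a brute-force scan", {
  t_traj <- c(0, 3, 3, 0, 0, 3, 0, 3, 3, 3)
  res <- spm_summarize(t_traj, 2.5)
  expect_equal(res$significant_fraction, 100 * 6 / 10)
  expect_equal(unname(res$regions),
               unname(cbind(c(1, 5, 7), c(3, 6, 10))))
  # all-false mask
  res0 <- spm_summarize(rep(0, 10), 2.5)
  expect_equal(res0$significant_fraction, 0)
  expect_equal(nrow(res0$regions), 0)
  # mask uses |t| >= critical value, two-sided
  res2 <- spm_summarize(c(-3, 0, 2.5), 2.5)
  expect_equal(res2$significant_mask, c(TRUE, FALSE, TRUE))
})

test_that("spm_compare runs per channel on study arrays", {
  study <- tiny_cohort(n_subpop = c(10L, 10L), n_hc = 12L,
                       n_followup = c(0L, 0L), recovery = c(0, 0),
                       magnitudes = c(4, 0), seed = 65)
  p <- prep_study(study)
  truth <- study$subjects$true_subpop[p$grp == "HOA"]
  sub1_rows <- which(p$grp == "HOA")[truth == 1]
  res <- spm_compare(p$z[sub1_rows, , , drop = FALSE],
                     p$z[p$grp == "HC", , , drop = FALSE],
                     design = "unpaired", n_perm = 300, seed = 8)
  expect_named(res, study$channels)
  # the planted channel is far more significant than an unaffected one
  expect_gt(res$hip_flexion_angle$significant_fraction, 50)
  expect_lt(res$knee_flexion_angle$significant_fraction, 30)
})
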