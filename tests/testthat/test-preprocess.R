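test_that("trial averaging equals the elementwise mean", {
  study <- tiny_cohort(n_subpop = c(3L, 3L), n_hc = 3L,
                       n_followup = c(0L, 0L), seed = 2)
  means <- average_trials(study)
  # brute-force loop oracle
  s <- 4; ch <- 2
  expect_equal(means[s, ch, ],
               (study$data[s, 1, ch, ] + study$data[s, 2, ch, ] +
                  study$data[s, 3, ch, ]) / 3)
  # idempotence on identical trials
  study$data[1, 2, , ] <- study$data[1, 1, , ]
  study$data[1, 3, , ] <- study$data[1, 1, , ]
  expect_equal(average_trials(study)[1, , ], study$data[1, 1, , ],
               ignore_attr = TRUE)
  # 0, 1, 2 at a point -> 1
  study$data[2, , 1, 1] <- c(0, 1, 2)
  expect_equal(average_trials(study)[2, 1, 1], 1)
  # missing trial -> error naming the subject
  study$data[3, 2, 1, 5] <- NA
  expect_error(average_trials(study), study$subjects$subject_id[3])
})

test_that("standardization statistics match the two-point formula and a
           loop oracle", {
  x <- array(0, dim = c(2, 1, 3))
  x[2, 1, ] <- 2
  st <- fit_standardization(x)
  expect_equal(drop(st$mean), rep(1, 3))
  expect_equal(drop(st$sd), rep(sqrt(2), 3))

  set.seed(30)
  y <- array(rnorm(50 * 2 * 7), dim = c(50, 2, 7))
  st2 <- fit_standardization(y)
  for (c_ in 1:2) for (t_ in 1:7) {
    expect_equal(st2$mean[c_, t_], mean(y[, c_, t_]))
    expect_equal(st2$sd[c_, t_], sd(y[, c_, t_]))
  }
})

test_that("degenerate zero-SD variables are an error naming the channel", {
  x <- array(rnorm(4 * 2 * 5), dim = c(4, 2, 5),
             dimnames = list(NULL, c("a", "b"), NULL))
  x[, 2, 3] <- 7
  expect_error(fit_standardization(x), "b.*timepoint 2")
})

test_that("HC self-standardization yields mean 0 and SD 1 at machine
           precision", {
  set.seed(31)
  hc <- array(rnorm(20 * 3 * 11, mean = 5, sd = 3), dim = c(20, 3, 11))
  st <- fit_standardization(hc)
  z <- standardize_waveforms(hc, st)
  expect_lt(max(abs(apply(z, c(2, 3), mean))), 1e-10)
  expect_lt(max(abs(apply(z, c(2, 3), sd) - 1)), 1e-10)
  # x = mean -> zeros
  one <- array(st$mean, dim = c(1, dim(st$mean)))
  expect_true(all(standardize_waveforms(aperm(one, c(1, 2, 3)), st) == 0))
  # shape mismatch
  expect_error(standardize_waveforms(hc[, , 1:5, drop = FALSE], st),
               "mismatch")
})

test_that("a planted two-SD offset standardizes to about two", {
  study <- generate_cohort(
    cohort_config(n_per_subpop = 60L, n_hc = 60L,
                  n_followup_per_subpop = 0L, recovery_fraction = 0,
                  seed = 33),
    tiny_channel_specs(),
    list(subpop_effect(1L, "hip_flexion_angle",
                       list(list(list(center = 0.5, width = 1e3,
                                      amplitude = 1))),  # ~constant offset
                       magnitude = 2)))
  means <- average_trials(study)
  grp <- study$subjects$group
  st <- fit_standardization(means[grp == "HC", , , drop = FALSE])
  z <- standardize_waveforms(means, st)
  hoa_mean <- mean(z[grp == "HOA", "hip_flexion_angle", ])
  expect_equal(hoa_mean, 2, tolerance = 0.15)
})

test_that("flattening is channel-major, invertible and 1818-dimensional on
           the standard grid", {
  set.seed(34)
  x <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5),
             dimnames = list(paste0("s", 1:3), paste0("ch", 1:4), NULL))
  m <- flatten_waveforms(x)
  expect_equal(dim(m), c(3, 20))
  # indexing law: (channel j, time t) -> column j*nt + t (0-based)
  for (j in 0:3) for (t_ in 0:4) {
    expect_equal(m[, j * 5 + t_ + 1], x[, j + 1, t_ + 1],
                 ignore_attr = TRUE)
  }
  back <- unflatten_waveforms(m, 4, 5, channels = paste0("ch", 1:4))
  expect_equal(back, x, ignore_attr = TRUE)

  full <- array(0, dim = c(2, 18, 101))
  expect_equal(ncol(flatten_waveforms(full)), 1818)
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(35)
  x <- matrix(rnorm(20 * 8), 20, 8)
  basis <- fit_pca(x, variance_threshold = 1)
  ev <- eigen(cov(x), symmetric = TRUE)
  expect_equal(basis$explained_variance_ratio_all[1:8],
               ev$values / sum(ev$values), tolerance = 1e-10)
  for (j in 1:8) {
    v <- ev$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_equal(basis$eigenvectors[, j], v, ignore_attr = TRUE,
                 tolerance = 1e-8)
  }
  # orthonormality
  g <- crossprod(basis$eigenvectors)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
})

test_that("retention rule keeps the minimal component count", {
  # rank-1 data -> single component explaining everything
  set.seed(36)
  u <- rnorm(12)
  line <- outer(u, c(1, 2, 3)) + matrix(5, 12, 3)
  b1 <- fit_pca(line, 0.9)
  expect_equal(b1$n_retained, 1L)
  expect_equal(sum(b1$explained_variance_ratio), 1, tolerance = 1e-12)

  x <- matrix(rnorm(40 * 5), 40, 5)
  b <- fit_pca(x, 0.9)
  expect_lte(b$n_retained, 5L)
  expect_gte(sum(b$explained_variance_ratio), 0.9)
  if (b$n_retained > 1) {
    expect_lt(sum(b$explained_variance_ratio[-b$n_retained]), 0.9)
  }
  # monotone in the threshold
  ks <- vapply(c(0.5, 0.7, 0.9, 0.99, 1), function(th) {
    fit_pca(x, th)$n_retained
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(fit_pca(x, 0), "variance_threshold")
  expect_error(fit_pca(x, 1.2), "variance_threshold")
})

test_that("projection reproduces the fitting cohort's scores and explains
           the retained variance", {
  set.seed(37)
  x <- matrix(rnorm(30 * 12), 30, 12) %*% diag(sqrt(12:1))
  basis <- fit_pca(x, 0.9)
  proj <- project_onto_basis(x, basis)
  expect_equal(proj$scores, basis$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  # a row equal to the center projects to zero
  z <- project_onto_basis(matrix(basis$center, 1), basis)
  expect_lt(max(abs(z$scores)), 1e-10)
  # reconstruction explains at least the threshold fraction of variance
  xc <- sweep(x, 2, basis$center)
  resid <- xc - proj$scores %*% t(basis$eigenvectors)
  expect_gte(1 - sum(resid^2) / sum(xc^2), 0.9)
  expect_error(project_onto_basis(x[, 1:5], basis), "columns")
})
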