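test_that("templates are bump superpositions evaluated on the grid", {
  spec <- list(channel_spec("x", "angle",
                            list(list(center = 0.5, width = 0.1,
                                      amplitude = 10))))
  tpl <- generate_templates(spec, 101L)
  grid <- seq(0, 1, length.out = 101)
  expect_equal(drop(tpl), 10 * exp(-0.5 * ((grid - 0.5) / 0.1)^2),
               ignore_attr = TRUE)
  expect_equal(which.max(tpl), which.min(abs(grid - 0.5)))

  zero <- list(channel_spec("x", "angle",
                            list(list(center = 0.5, width = 0.1,
                                      amplitude = 0))))
  expect_true(all(generate_templates(zero) == 0))

  expect_identical(generate_templates(tiny_channel_specs()),
                   generate_templates(tiny_channel_specs()))
})

test_that("channel specs are validated", {
  expect_error(channel_spec("x", "angle",
                            list(list(center = 0.5, width = 0,
                                      amplitude = 1))),
               "width")
  expect_error(generate_templates(list(
    channel_spec("a", "angle"), channel_spec("a", "moment"))),
    "unique")
})

test_that("cohort generation is deterministic and respects pairing", {
  s1 <- tiny_cohort(seed = 42)
  s2 <- tiny_cohort(seed = 42)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$subjects, s2$subjects)

  thr <- s1$subjects[s1$subjects$group == "THR", ]
  expect_true(all(!is.na(thr$paired_id)))
  expect_false(anyDuplicated(thr$paired_id) > 0)
  pre <- s1$subjects[match(thr$paired_id, s1$subjects$subject_id), ]
  expect_true(all(pre$group == "HOA"))
  expect_identical(thr$true_subpop, pre$true_subpop)
  expect_true(all(is.finite(s1$data)))
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(n_per_subpop = c(5, 5),
                             n_followup_per_subpop = c(6, 2),
                             recovery_fraction = c(0.5, 0.5)),
               "exceed")
  expect_error(cohort_config(recovery_fraction = c(0.5, 0.5)),
               "per subpopulation")
  expect_error(cohort_config(smoothness_lengthscale = 0), "lengthscale")
})

test_that("full recovery returns follow-up means to the healthy template", {
  # with zero noise the THR curves must equal the template exactly
  study <- generate_cohort(
    cohort_config(n_per_subpop = 4L, n_hc = 2L,
                  n_followup_per_subpop = 4L, recovery_fraction = 1,
                  trial_noise_sd = 0, subject_variation_sd = 0, seed = 5),
    tiny_channel_specs(),
    list(one_bump_effect(1L, "hip_flexion_angle", magnitude = 3)))
  tpl <- generate_templates(tiny_channel_specs())
  thr_rows <- which(study$subjects$group == "THR")
  for (r in thr_rows) {
    expect_equal(study$data[r, 1, , ], tpl, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # while the HOA partners still carry the planted effect
  hoa_rows <- which(study$subjects$group == "HOA")
  expect_gt(max(abs(study$data[hoa_rows[1], 1, , ] - tpl)), 1)
})

test_that("variance of the trial mean decomposes as subject + trial/n", {
  sv <- 1.3
  tn <- 0.9
  study <- generate_cohort(
    cohort_config(n_per_subpop = integer(0), n_hc = 1200L,
                  n_followup_per_subpop = integer(0),
                  recovery_fraction = numeric(0),
                  subject_variation_sd = sv, trial_noise_sd = tn,
                  n_trials = 3L, seed = 8),
    tiny_channel_specs()[1], list())
  means <- average_trials(study)
  v <- apply(means[, 1, ], 2, var)
  expected <- sv^2 + tn^2 / 3
  expect_equal(mean(v), expected, tolerance = 0.08)
})

test_that("planted effects are monotone in magnitude and confined to
           affected channels", {
  dev_for <- function(mag, seed = 21) {
    study <- generate_cohort(
      cohort_config(n_per_subpop = 40L, n_hc = 40L,
                    n_followup_per_subpop = 0L, recovery_fraction = 0,
                    seed = seed),
      tiny_channel_specs(),
      list(one_bump_effect(1L, "hip_flexion_angle", magnitude = mag)))
    means <- average_trials(study)
    grp <- study$subjects$group
    st <- fit_standardization(means[grp == "HC", , , drop = FALSE])
    z <- standardize_waveforms(means, st)
    hoa <- z[grp == "HOA", , , drop = FALSE]
    apply(hoa, 2, mean)  # mean standardized deviation per channel
  }
  d0 <- dev_for(0)
  d2 <- dev_for(2)
  d4 <- dev_for(4)
  expect_lt(abs(d0["hip_flexion_angle"]), 0.5)
  expect_gt(d2["hip_flexion_angle"], d0["hip_flexion_angle"] + 0.5)
  expect_gt(d4["hip_flexion_angle"], d2["hip_flexion_angle"] + 0.5)
  # unaffected channels stay near zero at every magnitude
  other <- setdiff(names(d4), "hip_flexion_angle")
  expect_true(all(abs(d4[other]) < 0.5))
})

test_that("null cohorts show no spurious group differences", {
  # magnitude 0: per-subject channel means of HOA vs HC pass a t-test at
  # alpha = 0.01 in almost all replicates
  p_vals <- vapply(1:30, function(s) {
    study <- generate_cohort(
      cohort_config(n_per_subpop = 15L, n_hc = 15L,
                    n_followup_per_subpop = 0L, recovery_fraction = 0,
                    seed = 100 + s),
      tiny_channel_specs()[1],
      list(one_bump_effect(1L, "hip_flexion_angle", magnitude = 0)))
    means <- apply(average_trials(study)[, 1, ], 1, mean)
    grp <- study$subjects$group
    t.test(means[grp == "HOA"], means[grp == "HC"])$p.value
  }, numeric(1))
  expect_gte(mean(p_vals > 0.01), 0.9)
})

test_that("CSV round trip preserves the study", {
  study <- tiny_cohort(n_subpop = c(3L, 3L), n_hc = 4L,
                       n_followup = c(2L, 2L), seed = 9)
  wf <- tempfile(fileext = ".csv")
  md <- tempfile(fileext = ".csv")
  write_study_csv(study, wf, md)
  back <- read_study_csv(wf, md)
  expect_equal(back$data, study$data, tolerance = 1e-10)
  expect_identical(back$subjects$subject_id, study$subjects$subject_id)
  expect_identical(back$subjects$group, study$subjects$group)
  expect_identical(back$subjects$paired_id, study$subjects$paired_id)
  expect_equal(back$subjects$walking_speed, study$subjects$walking_speed)
  unlink(c(wf, md))
})
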