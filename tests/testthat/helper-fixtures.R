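# Small cohorts and channel sets built in code for the tests.

# A four-channel set with simple bumps, cheap to generate.
tiny_channel_specs <- function() {
  list(
    channel_spec("hip_flexion_angle", "angle",
                 list(list(center = 0.3, width = 0.2, amplitude = 20))),
    channel_spec("knee_flexion_angle", "angle",
                 list(list(center = 0.6, width = 0.2, amplitude = 15))),
    channel_spec("hip_flexion_moment", "moment",
                 list(list(center = 0.2, width = 0.15, amplitude = 1))),
    channel_spec("ankle_plantarflexion_moment", "moment",
                 list(list(center = 0.75, width = 0.2, amplitude = 1.5)))
  )
}

one_bump_effect <- function(subpop_id, channels, magnitude, sign = 1) {
  subpop_effect(subpop_id, channels,
                lapply(seq_along(channels), function(i) {
                  list(list(center = 0.5, width = 0.3,
                            amplitude = sign))
                }),
                magnitude = magnitude)
}

tiny_cohort <- function(n_subpop = c(8L, 8L), n_hc = 10L,
                        n_followup = c(4L, 4L), recovery = c(0.9, 0.9),
                        magnitudes = c(3, 3), seed = 11L, ...) {
  specs <- tiny_channel_specs()
  effects <- list(
    one_bump_effect(1L, c("hip_flexion_angle", "hip_flexion_moment"),
                    magnitudes[1]),
    one_bump_effect(2L, c("knee_flexion_angle",
                          "ankle_plantarflexion_moment"),
                    magnitudes[2], sign = -1)
  )
  cfg <- cohort_config(n_per_subpop = n_subpop, n_hc = n_hc,
                       n_followup_per_subpop = n_followup,
                       recovery_fraction = recovery, seed = seed, ...)
  generate_cohort(cfg, specs, effects)
}

# standardized flattened matrices + basis for a study
prep_study <- function(study, variance_threshold = 0.9) {
  means <- average_trials(study)
  grp <- study$subjects$group
  st <- fit_standardization(means[grp == "HC", , , drop = FALSE])
  z <- standardize_waveforms(means, st)
  flat <- flatten_waveforms(z)
  basis <- fit_pca(flat[grp == "HOA", , drop = FALSE], variance_threshold)
  list(study = study, grp = grp, z = z, flat = flat, basis = basis,
       hoa = project_onto_basis(flat[grp == "HOA", , drop = FALSE], basis),
       hc = project_onto_basis(flat[grp == "HC", , drop = FALSE], basis),
       thr = if (any(grp == "THR"))
         project_onto_basis(flat[grp == "THR", , drop = FALSE], basis))
}

# Gaussian blobs in P dimensions for clustering tests
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}
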