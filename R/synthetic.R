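#' Planted subpopulation effect pattern
#'
#' Describes how one pathological subpopulation deviates from the healthy
#' template: a smooth offset curve per affected channel, scaled by a common
#' magnitude expressed in healthy-control standard-deviation units of the
#' per-subject mean waveform, so that `magnitude` reads directly as a
#' standardized effect size. Channels not listed receive no effect, and
#' `magnitude = 0` makes the subpopulation indistinguishable from healthy
#' controls in expectation.
#'
#' @param subpop_id Integer >= 1 identifying the subpopulation.
#' @param affected_channels Character vector of channel names.
#' @param effect_bumps List (one element per affected channel) of bump lists
#'   as in [channel_spec()]; each channel's curve is normalized to unit
#'   maximum absolute value before scaling, so amplitudes only set the shape.
#' @param magnitude Non-negative effect size in HC standard-deviation units.
#' @return An object of class `subpop_effect`.
#' @export
subpop_effect <- function(subpop_id, affected_channels, effect_bumps,
                          magnitude) {
  stopifnot(length(affected_channels) == length(effect_bumps),
            is.numeric(magnitude), length(magnitude) == 1L,
            is.finite(magnitude), magnitude >= 0,
            subpop_id >= 1)
  structure(list(subpop_id = as.integer(subpop_id),
                 affected_channels = affected_channels,
                 effect_bumps = effect_bumps,
                 magnitude = magnitude),
            class = "subpop_effect")
}

#' Default planted effects for three subpopulations
#'
#' Three effect patterns loosely emulating the qualitative adaptations seen
#' in hip-osteoarthritis gait: one strongly separable subpopulation with an
#' internally rotated, flexed hip and reduced sagittal hip moment; one
#' moderately separable subpopulation with external hip rotation and reduced
#' hip moments; and one mildly separable subpopulation with external hip
#' rotation, reduced hip adduction and increased anterior pelvic tilt.
#' Magnitudes 3, 2 and 1.5 HC standard deviations give decreasing
#' classifier separability.
#'
#' @return List of three [subpop_effect()] objects.
#' @export
default_subpop_effects <- function() {
  b <- function(center, width, amplitude) {
    list(list(center = center, width = width, amplitude = amplitude))
  }
  list(
    subpop_effect(1L,
      c("hip_rotation_angle", "hip_flexion_angle", "knee_flexion_angle",
        "hip_flexion_moment", "hip_rotation_moment"),
      list(b(0.5, 0.35, 1), b(0.45, 0.3, 1), b(0.5, 0.3, 1),
           b(0.6, 0.3, -1), b(0.55, 0.3, -1)),
      magnitude = 3),
    subpop_effect(2L,
      c("hip_rotation_angle", "hip_flexion_moment", "knee_flexion_angle",
        "hip_flexion_angle", "hip_rotation_moment"),
      list(b(0.5, 0.35, -1), b(0.4, 0.3, -1),
           c(b(0.15, 0.15, -1), b(0.85, 0.15, 1)),
           b(0.2, 0.2, -1), b(0.6, 0.3, -1)),
      magnitude = 2),
    subpop_effect(3L,
      c("hip_rotation_angle", "hip_adduction_angle", "hip_flexion_angle",
        "knee_rotation_angle", "pelvic_tilt"),
      list(b(0.5, 0.35, -1), b(0.4, 0.3, -1), b(0.5, 0.35, 1),
           b(0.5, 0.3, -1), b(0.7, 0.3, 1)),
      magnitude = 1.5)
  )
}

#' Synthetic cohort configuration
#'
#' Cohort shape and noise structure for [generate_cohort()]. The defaults
#' mirror a three-subpopulation study of 109 pre-surgery patients (HOA), 63
#' re-examined after total hip replacement (THR) and 56 healthy controls
#' (HC), measured over three trials on a 101-point stance grid.
#'
#' @param n_per_subpop Integer vector, HOA subjects per subpopulation.
#' @param n_hc Number of healthy controls.
#' @param n_followup_per_subpop Integer vector, paired post-surgery subjects
#'   per subpopulation (each at most the matching `n_per_subpop`).
#' @param recovery_fraction Numeric vector in \[0, 1\] per subpopulation; the
#'   planted effect magnitude after surgery is `magnitude * (1 - recovery)`.
#' @param trial_noise_sd SD of independent within-subject trial noise (raw
#'   waveform units).
#' @param subject_variation_sd SD of the smooth between-subject deviation
#'   curves (raw waveform units).
#' @param smoothness_lengthscale Correlation lengthscale of subject
#'   deviations on the \[0, 1\] stance grid; in (0, 1\].
#' @param n_trials Trials per subject (default 3).
#' @param n_timepoints Stance grid size (default 101).
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_subpop = c(28L, 44L, 37L),
                          n_hc = 56L,
                          n_followup_per_subpop = c(16L, 28L, 19L),
                          recovery_fraction = c(0.8, 0.4, 0.7),
                          trial_noise_sd = 0.5,
                          subject_variation_sd = 1,
                          smoothness_lengthscale = 0.3,
                          n_trials = 3L,
                          n_timepoints = 101L,
                          seed = 1L) {
  k <- length(n_per_subpop)
  if (length(n_followup_per_subpop) != k || length(recovery_fraction) != k) {
    stop("n_per_subpop, n_followup_per_subpop and recovery_fraction must ",
         "have one entry per subpopulation", call. = FALSE)
  }
  if (any(n_per_subpop < 0) || n_hc < 0 || any(n_followup_per_subpop < 0)) {
    stop("cohort counts must be non-negative", call. = FALSE)
  }
  if (any(n_followup_per_subpop > n_per_subpop)) {
    stop("n_followup_per_subpop may not exceed n_per_subpop", call. = FALSE)
  }
  if (any(recovery_fraction < 0 | recovery_fraction > 1)) {
    stop("recovery_fraction entries must lie in [0, 1]", call. = FALSE)
  }
  if (trial_noise_sd < 0 || subject_variation_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (smoothness_lengthscale <= 0 || smoothness_lengthscale > 1) {
    stop("smoothness_lengthscale must lie in (0, 1]", call. = FALSE)
  }
  if (n_trials < 1 || n_timepoints < 2) {
    stop("need n_trials >= 1 and n_timepoints >= 2", call. = FALSE)
  }
  structure(list(n_per_subpop = as.integer(n_per_subpop),
                 n_hc = as.integer(n_hc),
                 n_followup_per_subpop = as.integer(n_followup_per_subpop),
                 recovery_fraction = recovery_fraction,
                 trial_noise_sd = trial_noise_sd,
                 subject_variation_sd = subject_variation_sd,
                 smoothness_lengthscale = smoothness_lengthscale,
                 n_trials = as.integer(n_trials),
                 n_timepoints = as.integer(n_timepoints),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Cholesky factor of a squared-exponential covariance on the stance grid,
# used to draw smooth between-subject deviation curves.
smooth_cov_chol <- function(grid, lengthscale) {
  d <- outer(grid, grid, `-`)
  k <- exp(-0.5 * (d / lengthscale)^2)
  chol(k + diag(1e-8, length(grid)))
}

# Evaluate an effect's per-channel offset curves on the grid, normalized to
# unit maximum absolute value, as a [n_channels x n_timepoints] matrix
# (zero rows for unaffected channels).
effect_curves <- function(effect, channel_specs, grid) {
  nm <- channel_names(channel_specs)
  out <- matrix(0, length(nm), length(grid), dimnames = list(nm, NULL))
  missing <- setdiff(effect$affected_channels, nm)
  if (length(missing)) {
    stop("effect for subpopulation ", effect$subpop_id,
         " names unknown channels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(effect$affected_channels)) {
    y <- eval_bumps(effect$effect_bumps[[i]], grid)
    m <- max(abs(y))
    if (m > 0) y <- y / m
    out[effect$affected_channels[i], ] <- y
  }
  out
}

#' Generate a synthetic gait-waveform study
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: per-channel healthy template curves, smooth correlated
#' between-subject deviation (squared-exponential covariance with tunable
#' lengthscale, independent across channels), independent per-trial noise,
#' planted subpopulation effect patterns confined to chosen channels, and a
#' paired post-surgery cohort whose planted effects shrink toward the
#' healthy template by a per-subpopulation recovery fraction. Post-surgery
#' subjects keep their pre-surgery partner's deviation curves (same person)
#' but receive fresh trial noise. Scalar metadata (age, sex, body mass,
#' height, walking speed) are drawn from group-level distributions and do
#' not influence the waveforms.
#'
#' Effects are added as `magnitude * sd_ref * curve`, where `sd_ref` is the
#' theoretical HC standard deviation of the trial-averaged waveform,
#' `sqrt(subject_variation_sd^2 + trial_noise_sd^2 / n_trials)`, so that
#' `magnitude` is a standardized effect size.
#'
#' @param config A [cohort_config()].
#' @param channel_specs List of [channel_spec()]s (default the 18-channel
#'   standard set).
#' @param effects List of [subpop_effect()]s, one per subpopulation.
#' @return An object of class `waveform_study`: a list with `subjects` (a
#'   data frame with subject_id, group, true_subpop, paired_id and
#'   metadata), `data` (array `[subject x trial x channel x timepoint]`),
#'   `channels`, `channel_kind` and `grid`.
#' @examples
#' cfg <- cohort_config(n_per_subpop = c(5, 5), n_hc = 6,
#'                      n_followup_per_subpop = c(3, 3),
#'                      recovery_fraction = c(0.8, 0.8), seed = 7)
#' study <- generate_cohort(cfg, effects = default_subpop_effects()[1:2])
#' table(study$subjects$group)
#' @export
generate_cohort <- function(config,
                            channel_specs = default_channel_specs(),
                            effects = default_subpop_effects()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_channel_specs(channel_specs)
  k <- length(config$n_per_subpop)
  if (length(effects) != k) {
    stop("need one subpop_effect per subpopulation (", k, "), got ",
         length(effects), call. = FALSE)
  }
  nt <- config$n_timepoints
  nc <- length(channel_specs)
  ntr <- config$n_trials
  grid <- seq(0, 1, length.out = nt)
  templates <- generate_templates(channel_specs, nt)
  L <- smooth_cov_chol(grid, config$smoothness_lengthscale)
  sd_ref <- sqrt(config$subject_variation_sd^2 +
                   config$trial_noise_sd^2 / ntr)
  if (sd_ref == 0) sd_ref <- 1
  eff_mat <- lapply(effects, effect_curves, channel_specs = channel_specs,
                    grid = grid)

  n_hoa <- sum(config$n_per_subpop)
  n_rec <- n_hoa + sum(config$n_followup_per_subpop) + config$n_hc
  data <- array(NA_real_, dim = c(n_rec, ntr, nc, nt))
  subjects <- data.frame(subject_id = character(n_rec),
                         group = character(n_rec),
                         true_subpop = NA_integer_,
                         paired_id = NA_character_,
                         stringsAsFactors = FALSE)

  set.seed(config$seed)
  draw_subject_dev <- function() {
    # [channel x timepoint] smooth deviation, independent per channel
    z <- matrix(stats::rnorm(nt * nc), nt, nc)
    t(crossprod(L, z)) * config$subject_variation_sd
  }
  draw_trials <- function(mean_ct) {
    out <- array(NA_real_, dim = c(ntr, nc, nt))
    for (tr in seq_len(ntr)) {
      out[tr, , ] <- mean_ct +
        matrix(stats::rnorm(nc * nt, sd = config$trial_noise_sd), nc, nt)
    }
    out
  }

  row <- 0L
  # HC subjects
  for (i in seq_len(config$n_hc)) {
    row <- row + 1L
    mean_ct <- templates + draw_subject_dev()
    data[row, , , ] <- draw_trials(mean_ct)
    subjects$subject_id[row] <- sprintf("HC%03d", i)
    subjects$group[row] <- "HC"
  }
  # HOA subjects, with the THR partner drawn immediately after so the
  # pairing shares the subject deviation
  hoa_i <- 0L
  thr_i <- 0L
  for (kk in seq_len(k)) {
    mag <- effects[[kk]]$magnitude
    planted <- mag * sd_ref * eff_mat[[kk]]
    for (i in seq_len(config$n_per_subpop[kk])) {
      row <- row + 1L
      hoa_i <- hoa_i + 1L
      dev <- draw_subject_dev()
      data[row, , , ] <- draw_trials(templates + dev + planted)
      hoa_id <- sprintf("HOA%03d", hoa_i)
      subjects$subject_id[row] <- hoa_id
      subjects$group[row] <- "HOA"
      subjects$true_subpop[row] <- kk
      if (i <= config$n_followup_per_subpop[kk]) {
        row <- row + 1L
        thr_i <- thr_i + 1L
        shrunk <- planted * (1 - config$recovery_fraction[kk])
        data[row, , , ] <- draw_trials(templates + dev + shrunk)
        subjects$subject_id[row] <- sprintf("THR%03d", thr_i)
        subjects$group[row] <- "THR"
        subjects$true_subpop[row] <- kk
        subjects$paired_id[row] <- hoa_id
      }
    }
  }

  # Metadata: group-level distributions, no influence on waveforms.
  n <- nrow(subjects)
  subjects$age <- round(stats::rnorm(n, 62, 10), 1)
  subjects$sex <- sample(c("m", "f"), n, replace = TRUE)
  subjects$mass <- round(ifelse(subjects$group == "HC",
                                stats::rnorm(n, 69, 12),
                                stats::rnorm(n, 80.5, 14.6)), 1)
  subjects$height <- round(stats::rnorm(n, 1.70, 0.09), 2)
  speed_mu <- c(HOA = 1.01, THR = 1.17, HC = 1.32)
  speed_sd <- c(HOA = 0.19, THR = 0.15, HC = 0.15)
  subjects$walking_speed <- round(stats::rnorm(n, speed_mu[subjects$group],
                                               speed_sd[subjects$group]), 2)
  # THR metadata that should match the pre-surgery person
  thr <- which(subjects$group == "THR")
  if (length(thr)) {
    pre <- match(subjects$paired_id[thr], subjects$subject_id)
    subjects$sex[thr] <- subjects$sex[pre]
    subjects$height[thr] <- subjects$height[pre]
    subjects$age[thr] <- round(subjects$age[pre] + 1.2, 1)
  }

  dimnames(data) <- list(subjects$subject_id,
                         sprintf("trial%d", seq_len(ntr)),
                         channel_names(channel_specs),
                         sprintf("t%03d", seq_len(nt) - 1L))
  structure(list(subjects = subjects,
                 data = data,
                 channels = channel_names(channel_specs),
                 channel_kind = vapply(channel_specs, `[[`, "", "kind"),
                 grid = grid),
            class = "waveform_study")
}

#' @export
print.waveform_study <- function(x, ...) {
  cat("waveform_study:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(table(x$subjects$group)),
                    table(x$subjects$group)), collapse = ", "),
      "), ", dim(x$data)[2], "trials x", dim(x$data)[3], "channels x",
      dim(x$data)[4], "timepoints\n")
  invisible(x)
}

#' Write / read a waveform study as plain CSV
#'
#' The waveform table is wide: one row per subject x trial x channel with
#' columns `subject_id, group, true_subpop, paired_id, trial, channel,
#' t000...`; scalar metadata go to a companion CSV keyed by `subject_id`.
#'
#' @param study A `waveform_study`.
#' @param waveform_csv,metadata_csv File paths.
#' @return `write_study_csv` invisibly returns the paths; `read_study_csv`
#'   returns a `waveform_study`.
#' @export
write_study_csv <- function(study, waveform_csv, metadata_csv) {
  d <- study$data
  ns <- dim(d)[1]; ntr <- dim(d)[2]; nc <- dim(d)[3]; nt <- dim(d)[4]
  # rows ordered subject-major, then trial, then channel
  flat <- matrix(aperm(d, c(4, 3, 2, 1)), nrow = nt)
  wide <- as.data.frame(t(flat))
  names(wide) <- sprintf("t%03d", seq_len(nt) - 1L)
  idx <- expand.grid(channel = study$channels,
                     trial = seq_len(ntr),
                     s = seq_len(ns), stringsAsFactors = FALSE)
  sub <- study$subjects[idx$s, c("subject_id", "group", "true_subpop",
                                 "paired_id")]
  out <- cbind(sub, trial = idx$trial, channel = idx$channel, wide)
  utils::write.csv(out, waveform_csv, row.names = FALSE)
  meta_cols <- c("subject_id", "age", "sex", "mass", "height",
                 "walking_speed")
  utils::write.csv(study$subjects[, meta_cols], metadata_csv,
                   row.names = FALSE)
  invisible(c(waveform_csv, metadata_csv))
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(waveform_csv, metadata_csv) {
  wide <- utils::read.csv(waveform_csv, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  tcols <- grep("^t\\d{3}$", names(wide), value = TRUE)
  nt <- length(tcols)
  channels <- unique(wide$channel)
  nc <- length(channels)
  trials <- sort(unique(wide$trial))
  ntr <- length(trials)
  ids <- unique(wide$subject_id)
  ns <- length(ids)
  if (nrow(wide) != ns * ntr * nc) {
    stop("waveform CSV is not a complete subject x trial x channel grid",
         call. = FALSE)
  }
  d <- array(NA_real_, dim = c(ns, ntr, nc, nt),
             dimnames = list(ids, sprintf("trial%d", trials), channels,
                             tcols))
  m <- as.matrix(wide[, tcols])
  for (r in seq_len(nrow(wide))) {
    d[match(wide$subject_id[r], ids), match(wide$trial[r], trials),
      match(wide$channel[r], channels), ] <- m[r, ]
  }
  first <- wide[!duplicated(wide$subject_id),
                c("subject_id", "group", "true_subpop", "paired_id")]
  subjects <- merge(first, meta, by = "subject_id", sort = FALSE)
  subjects <- subjects[match(ids, subjects$subject_id), ]
  rownames(subjects) <- NULL
  subjects$paired_id <- as.character(subjects$paired_id)
  structure(list(subjects = subjects, data = d, channels = channels,
                 channel_kind = rep(NA_character_, nc),
                 grid = seq(0, 1, length.out = nt)),
            class = "waveform_study")
}
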