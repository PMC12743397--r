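#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. The defaults reproduce
#' the reference settings: 90% PCA variance retention, five k-means runs,
#' 10-fold cross-validation, box constraint and kernel scale 1, two-sided
#' alpha 0.05, and the five most important waveforms per subpopulation.
#'
#' @param synthetic A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when reading from CSV.
#' @param channel_specs Channel set (default the 18-channel standard set).
#' @param effects Planted effects for the synthetic cohort.
#' @param waveform_csv,metadata_csv Optional CSV paths; when both are given
#'   the study is read from disk instead of generated.
#' @param variance_threshold PCA retention threshold (default 0.90).
#' @param k_min,k_max Cluster-count search range for the Ward step.
#' @param n_kmeans_runs Repeated k-means runs (default 5).
#' @param cv_folds Cross-validation folds (default 10).
#' @param box_constraint,kernel_scale Linear-SVM settings (default 1, 1).
#' @param alpha Two-sided family-wise level for waveform inference.
#' @param n_perm Permutation budget per channel (default 1000).
#' @param top_k Number of most-important waveforms per subpopulation.
#' @param seed Master seed; per-stage seeds are derived by fixed offsets.
#' @param output_dir Optional directory; when set, [run_pipeline()] writes
#'   all result tables as CSV.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = cohort_config(),
                            channel_specs = default_channel_specs(),
                            effects = default_subpop_effects(),
                            waveform_csv = NULL, metadata_csv = NULL,
                            variance_threshold = 0.90,
                            k_min = 2L, k_max = 10L,
                            n_kmeans_runs = 5L, cv_folds = 10L,
                            box_constraint = 1, kernel_scale = 1,
                            alpha = 0.05, n_perm = 1000L, top_k = 5L,
                            seed = 1L, output_dir = NULL) {
  structure(list(synthetic = synthetic, channel_specs = channel_specs,
                 effects = effects, waveform_csv = waveform_csv,
                 metadata_csv = metadata_csv,
                 variance_threshold = variance_threshold,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_kmeans_runs = as.integer(n_kmeans_runs),
                 cv_folds = as.integer(cv_folds),
                 box_constraint = box_constraint,
                 kernel_scale = kernel_scale,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full subpopulation-discovery and surgical-response workflow
#'
#' Executes, in order: cohort generation (or CSV load), trial averaging,
#' HC-referenced standardization, flattening, PCA on the HOA cohort and
#' projection of all cohorts, Ward cluster-count selection, consensus
#' k-means assignment with consistency filtering, one linear SVM per
#' subpopulation versus HC with cross-validated metrics, projection of the
#' paired post-surgery subjects through the final models, Shapley
#' back-projection to per-waveform importance, COGS for pre- and
#' post-surgery subjects, and permutation-SPM comparisons (each
#' subpopulation versus HC, and paired pre/post) on the top-k channels.
#' Deterministic given the master seed. When `config$output_dir` is set,
#' all tables are written as CSV.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `gait_run_report`: `study`, `basis`, `k`,
#'   `assignments`, `scores` (per-cohort reduced features),
#'   `classification` (Table-3-shaped data frame, pre and post rows),
#'   `importance` (list of profiles), `cogs` (data frame), `spm_vs_hc` and
#'   `spm_pre_post` (lists of `spm_result` lists), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  study <- stage_fail("data", {
    if (!is.null(config$waveform_csv) && !is.null(config$metadata_csv)) {
      read_study_csv(config$waveform_csv, config$metadata_csv)
    } else {
      cfg <- config$synthetic
      cfg$seed <- seed
      generate_cohort(cfg, config$channel_specs, config$effects)
    }
  })

  prep <- stage_fail("preprocess", {
    means <- average_trials(study)
    grp <- study$subjects$group
    hc <- means[grp == "HC", , , drop = FALSE]
    stats <- fit_standardization(hc)
    z <- standardize_waveforms(means, stats)
    flat <- flatten_waveforms(z)
    basis <- fit_pca(flat[grp == "HOA", , drop = FALSE],
                     config$variance_threshold)
    list(z = z, flat = flat, basis = basis, stats = stats,
         scores = lapply(c(HOA = "HOA", THR = "THR", HC = "HC"), function(g) {
           project_onto_basis(flat[grp == g, , drop = FALSE], basis,
                              subject_ids = study$subjects$subject_id[grp == g],
                              group = g)
         }))
  })

  clus <- stage_fail("subpopulations", {
    k <- ward_select_k(prep$scores$HOA, config$k_min, config$k_max)
    assign <- kmeans_consensus(prep$scores$HOA, k,
                               n_runs = config$n_kmeans_runs,
                               seed = seed + 1000L)
    list(k = as.integer(k), gaps = attr(k, "gaps"),
         heights = attr(k, "heights"), assignments = assign)
  })

  subj <- study$subjects
  hoa_ids <- subj$subject_id[subj$group == "HOA"]
  hc_scores <- prep$scores$HC$scores
  thr_ids <- subj$subject_id[subj$group == "THR"]
  thr_pairs <- subj$paired_id[subj$group == "THR"]

  class_rows <- list()
  importance <- list()
  cogs_rows <- list()
  spm_vs_hc <- list()
  spm_pre_post <- list()
  grp <- subj$group

  for (j in seq_len(clus$k)) {
    label_j <- !is.na(clus$assignments$label) & clus$assignments$label == j
    members <- clus$assignments$subject_id[label_j]
    if (length(members) < 2) next
    sub_scores <- prep$scores$HOA$scores[match(members, hoa_ids), ,
                                         drop = FALSE]
    cv <- stage_fail(paste0("svm_classify subpop ", j), {
      crossvalidate_10fold(sub_scores, hc_scores, seed = seed + 2000L + j,
                           n_folds = config$cv_folds,
                           box_constraint = config$box_constraint,
                           kernel_scale = config$kernel_scale,
                           subpop_id = j)
    })
    class_rows[[length(class_rows) + 1L]] <- cv$report
    model <- cv$final_model

    prof <- stage_fail(paste0("explain subpop ", j), {
      waveform_importance(model, sub_scores, prep$basis, study$channels,
                          subpop_id = j)
    })
    importance[[j]] <- prof
    top <- top_k(prof, min(config$top_k, length(study$channels)))

    # COGS pre for all members
    cg_pre <- cogs(model, score_vector = sub_scores)
    cogs_rows[[length(cogs_rows) + 1L]] <- data.frame(
      subject_id = members, subpop = j, era = "pre", cogs = cg_pre,
      stringsAsFactors = FALSE)

    # follow-up subjects of this subpopulation
    fu_ids <- thr_ids[thr_pairs %in% members]
    if (length(fu_ids)) {
      fu_scores <- prep$scores$THR$scores[match(fu_ids, thr_ids), ,
                                          drop = FALSE]
      class_rows[[length(class_rows) + 1L]] <-
        project_followup(model, fu_scores, hc_scores, subpop_id = j)
      cg_post <- cogs(model, score_vector = fu_scores)
      cogs_rows[[length(cogs_rows) + 1L]] <- data.frame(
        subject_id = fu_ids, subpop = j, era = "post", cogs = cg_post,
        stringsAsFactors = FALSE)
    }

    spm_vs_hc[[j]] <- stage_fail(paste0("spm subpop ", j, " vs HC"), {
      spm_compare(prep$z[match(members, subj$subject_id), , , drop = FALSE],
                  prep$z[grp == "HC", , , drop = FALSE],
                  design = "unpaired", channels = top,
                  alpha = config$alpha, n_perm = config$n_perm,
                  seed = seed + 3000L + 20L * j)
    })
    if (length(fu_ids) >= 4) {  # 2^n >= 10 distinct sign-flip patterns
      pre_paired <- prep$z[match(thr_pairs[match(fu_ids, thr_ids)],
                                 subj$subject_id), , , drop = FALSE]
      post_paired <- prep$z[match(fu_ids, subj$subject_id), , , drop = FALSE]
      spm_pre_post[[j]] <- stage_fail(paste0("spm subpop ", j, " pre/post"), {
        spm_compare(pre_paired, post_paired, design = "paired",
                    channels = top, alpha = config$alpha,
                    n_perm = config$n_perm,
                    seed = seed + 4000L + 20L * j)
      })
    }
  }

  report <- structure(list(
    study = study,
    basis = prep$basis,
    standardization = prep$stats,
    standardized = prep$z,
    k = clus$k,
    ward_gaps = clus$gaps,
    ward_heights = clus$heights,
    assignments = clus$assignments,
    scores = prep$scores,
    classification = do.call(rbind, class_rows),
    importance = importance,
    cogs = do.call(rbind, cogs_rows),
    spm_vs_hc = spm_vs_hc,
    spm_pre_post = spm_pre_post,
    provenance = list(seed = seed,
                      config = config[setdiff(names(config),
                                              c("channel_specs", "effects"))],
                      n_channels = length(study$channels),
                      package_version = as.character(
                        utils::packageVersion("gaitsubpop")),
                      r_version = R.version.string)),
    class = "gait_run_report")

  if (!is.null(config$output_dir)) write_report_csv(report, config$output_dir)
  report
}

#' @export
print.gait_run_report <- function(x, ...) {
  cat("gait_run_report:", x$k, "subpopulations;",
      sum(!x$assignments$consistent), "excluded;",
      x$basis$n_retained, "PCs\n")
  print(x$classification, row.names = FALSE)
  invisible(x)
}

#' Write the report tables as CSV
#'
#' Writes assignments, the classification table, waveform importances, the
#' COGS table, SPM significant fractions, PC scores and the dendrogram
#' heights to `dir`.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$assignments, "assignments.csv")
  wr(report$classification, "classification.csv")
  imp <- do.call(rbind, lapply(report$importance, function(p) {
    data.frame(subpop = p$subpop, rank = seq_along(p$ranking),
               channel = p$ranking,
               importance = unname(p$importance[p$ranking]),
               stringsAsFactors = FALSE)
  }))
  wr(imp, "importance.csv")
  wr(report$cogs, "cogs.csv")
  frac <- do.call(rbind, lapply(seq_along(report$spm_vs_hc), function(j) {
    res <- report$spm_vs_hc[[j]]
    if (is.null(res)) return(NULL)
    data.frame(subpop = j, comparison = "subpop_vs_hc",
               channel = names(res),
               significant_fraction = vapply(res, `[[`, 0,
                                             "significant_fraction"),
               stringsAsFactors = FALSE)
  }))
  frac2 <- do.call(rbind, lapply(seq_along(report$spm_pre_post), function(j) {
    res <- report$spm_pre_post[[j]]
    if (is.null(res)) return(NULL)
    data.frame(subpop = j, comparison = "pre_vs_post",
               channel = names(res),
               significant_fraction = vapply(res, `[[`, 0,
                                             "significant_fraction"),
               stringsAsFactors = FALSE)
  }))
  wr(rbind(frac, frac2), "spm_fractions.csv")
  scores <- do.call(rbind, lapply(report$scores, function(s) {
    data.frame(subject_id = s$subject_ids, group = s$group, s$scores,
               stringsAsFactors = FALSE)
  }))
  wr(scores, "scores.csv")
  wr(data.frame(merge_index = seq_along(report$ward_heights),
                height = report$ward_heights), "dendrogram_heights.csv")
  jsonlite::write_json(report$provenance[c("seed", "n_channels",
                                           "package_version", "r_version")],
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(paths)
}

#' Figures for a pipeline report
#'
#' Builds (and optionally saves as PNG) the three standard views: a PC1-PC2
#' scatter with a convex hull per subpopulation, per-channel mean and SD
#' overlays of each subpopulation against HC with significant regions
#' shaded, and pre/post COGS violins per subpopulation.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Optional output directory; when given, PNGs are written.
#' @return Invisibly, a named list of ggplot objects.
#' @export
make_figures <- function(report, dir = NULL) {
  stopifnot(inherits(report, "gait_run_report"))
  if (is.null(report$classification) || nrow(report$assignments) == 0) {
    stop("empty report", call. = FALSE)
  }
  figs <- list()

  sc <- report$scores$HOA$scores
  asg <- report$assignments
  df <- data.frame(pc1 = sc[, 1], pc2 = sc[, 2],
                   subpop = ifelse(is.na(asg$label), "excluded",
                                   paste0("HOA", asg$label)))
  hulls <- do.call(rbind, lapply(split(df, df$subpop), function(d) {
    if (d$subpop[1] == "excluded" || nrow(d) < 3) return(NULL)
    d[grDevices::chull(d$pc1, d$pc2), ]
  }))
  figs$pc_scatter <- ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                                      colour = .data$subpop)) +
    ggplot2::geom_polygon(data = hulls,
                          ggplot2::aes(fill = .data$subpop),
                          alpha = 0.15, show.legend = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PC1", y = "PC2", colour = NULL,
                  title = "Subpopulations in the reduced feature space")

  subj <- report$study$subjects
  z <- report$standardized
  grid_pct <- seq(0, 100, length.out = dim(z)[3])
  wf <- list()
  for (j in seq_along(report$spm_vs_hc)) {
    res <- report$spm_vs_hc[[j]]
    if (is.null(res)) next
    members <- asg$subject_id[!is.na(asg$label) & asg$label == j]
    for (ch in names(res)) {
      for (g in c("subpop", "HC")) {
        rows <- if (g == "HC") subj$group == "HC" else
          subj$subject_id %in% members
        m <- z[rows, ch, , drop = TRUE]
        wf[[length(wf) + 1L]] <- data.frame(
          subpop = paste0("HOA", j), channel = ch, stance = grid_pct,
          group = if (g == "HC") "HC" else paste0("HOA", j),
          mean = colMeans(m), sd = apply(m, 2, stats::sd))
      }
    }
  }
  shade <- do.call(rbind, lapply(seq_along(report$spm_vs_hc), function(j) {
    res <- report$spm_vs_hc[[j]]
    if (is.null(res)) return(NULL)
    do.call(rbind, lapply(names(res), function(ch) {
      rg <- res[[ch]]$regions
      if (!nrow(rg)) return(NULL)
      n <- length(res[[ch]]$t_trajectory)
      data.frame(subpop = paste0("HOA", j), channel = ch,
                 xmin = 100 * rg[, "start"] / (n - 1),
                 xmax = 100 * pmin(rg[, "end"] - 1, n - 1) / (n - 1))
    }))
  }))
  wf <- do.call(rbind, wf)
  if (!is.null(wf)) {
    p <- ggplot2::ggplot(wf, ggplot2::aes(.data$stance, .data$mean,
                                          colour = .data$group,
                                          fill = .data$group))
    if (!is.null(shade) && nrow(shade)) {
      p <- p + ggplot2::geom_rect(data = shade,
                                  ggplot2::aes(xmin = .data$xmin,
                                               xmax = .data$xmax),
                                  ymin = -Inf, ymax = Inf,
                                  inherit.aes = FALSE, alpha = 0.25,
                                  fill = "grey70")
    }
    figs$waveforms <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           alpha = 0.25, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(channel ~ subpop, scales = "free_y") +
      ggplot2::labs(x = "Stance phase [%]", y = "Standardized signal",
                    colour = NULL, fill = NULL,
                    title = "Most important waveforms vs healthy controls")
  }

  cg <- report$cogs
  if (!is.null(cg) && nrow(cg)) {
    cg$era <- factor(cg$era, levels = c("pre", "post"))
    figs$cogs_violin <- ggplot2::ggplot(cg,
        ggplot2::aes(factor(.data$subpop), .data$cogs, fill = .data$era)) +
      ggplot2::geom_violin(position = ggplot2::position_dodge(0.8),
                           trim = FALSE) +
      ggplot2::labs(x = "Subpopulation", y = "COGS", fill = NULL,
                    title = "Classifier-oriented gait score before/after surgery")
  }

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sizes <- list(pc_scatter = c(6, 5), waveforms = c(10, 12),
                  cogs_violin = c(6, 4))
    for (nm in names(figs)) {
      ggplot2::ggsave(file.path(dir, paste0(nm, ".png")), figs[[nm]],
                      width = sizes[[nm]][1], height = sizes[[nm]][2],
                      dpi = 150)
    }
  }
  invisible(figs)
}

#' @importFrom rlang .data
NULL
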