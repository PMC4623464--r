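#' Run the full analysis pipeline on a dataset
#'
#' Reproduces the study's complete Results workflow on a (simulated or
#' imported) dataset:
#' \enumerate{
#'   \item treatment phase: per-participant stop metrics, race-model
#'     validity test, and exclusion of participants with out-of-range
#'     p(stop) or SSRT or an invalid race;
#'   \item knowledge classification from the debrief;
#'   \item valuation phase: devaluation scores, per-group 1.5 x IQR
#'     outlier removal, and the 2 x 2 x 4 mixed ANOVA on mean bidding
#'     level (outliers excluded);
#'   \item within-subjects contrast of explicitly vs implicitly
#'     represented shape pairs in explicit learners;
#'   \item control analyses on the full (unfiltered) sample: Wilcoxon
#'     signed-rank test of stop vs go bid levels and Mann-Whitney test of
#'     devaluation scores between knowledge groups;
#'   \item bidding-variance ANOVA and named-vs-unnamed variance contrast;
#'   \item implicit learners: within-group 2 x 4 ANOVA and the
#'     Cook's-screened variance-devaluation correlation.
#' }
#'
#' @param dataset A `devalsim_dataset`.
#' @param p_stop_bounds,ssrt_bounds Stop-task exclusion bounds.
#' @param iqr_k IQR multiplier for the devaluation-score outlier filter.
#' @return A list of class `devalsim_report` with one element per results
#'   section.
#' @export
analyze_study <- function(dataset, p_stop_bounds = c(0.4, 0.6),
                          ssrt_bounds = c(120, 300), iqr_k = 1.5) {
  stopifnot(inherits(dataset, "devalsim_dataset"))
  config <- dataset$config

  metrics <- stop_metrics_by_participant(dataset$treatment)
  race <- check_race_validity(metrics)
  excl <- apply_exclusions(metrics, p_stop_bounds, ssrt_bounds)
  kept_ids <- excl$retained$participant

  knowledge <- classify_cohort_knowledge(dataset)
  knowledge <- knowledge[knowledge$participant %in% kept_ids, ]

  scores <- devaluation_scores(dataset$auction, config)
  scores <- scores[scores$participant %in% kept_ids, ]
  scores <- dplyr::left_join(scores, knowledge, by = "participant")
  filt <- iqr_outlier_filter(scores$devaluation_score, scores$knowledge,
                             k = iqr_k)
  analysis_ids <- scores$participant[filt$retained]
  outlier_ids <- scores$participant[!filt$retained]

  cells <- bid_cell_summaries(dataset$auction, config, knowledge)
  cells_kept <- cells[cells$participant %in% analysis_ids, ]
  main_anova <- if (length(unique(cells_kept$knowledge)) == 2L) {
    mixed_anova_2x2x4(cells_kept)
  } else {
    within_anova_2x4(cells_kept)
  }

  subset_for <- function(ids) {
    ds <- dataset
    ds$auction <- ds$auction[ds$auction$participant %in% ids, ]
    ds$stimuli <- ds$stimuli[ds$stimuli$participant %in% ids, ]
    ds$debriefs <- ds$debriefs[intersect(names(ds$debriefs), ids)]
    ds
  }

  within_subj <- tryCatch(
    within_subjects_pair_analysis(subset_for(kept_ids), knowledge),
    error = function(e) NULL
  )

  # control analyses keep the IQR outliers in (full stop-task-retained set)
  stop_levels <- dplyr::summarise(
    dplyr::group_by(cells, .data$participant, .data$stopping),
    level = mean(.data$mean_bid_level), .groups = "drop"
  )
  wide <- merge(
    stop_levels[stop_levels$stopping == "go", c("participant", "level")],
    stop_levels[stop_levels$stopping == "stop", c("participant", "level")],
    by = "participant", suffixes = c("_go", "_stop")
  )
  wilcoxon <- wilcoxon_signed_rank(wide$level_go, wide$level_stop)
  mw <- NULL
  if (length(unique(scores$knowledge)) == 2L) {
    mw <- mann_whitney_u(
      scores$devaluation_score[scores$knowledge == "explicit"],
      scores$devaluation_score[scores$knowledge == "implicit"]
    )
  }

  variance <- tryCatch(
    bidding_variance_analysis(subset_for(analysis_ids), knowledge,
                              participants = analysis_ids),
    error = function(e) NULL
  )

  implicit_ids <- knowledge$participant[knowledge$knowledge == "implicit"]
  implicit_anova <- if (length(implicit_ids) >= 3L) {
    within_anova_2x4(cells[cells$participant %in% implicit_ids, ])
  }
  implicit_corr <- tryCatch(
    implicit_variance_devaluation_correlation(subset_for(kept_ids),
                                              knowledge),
    error = function(e) NULL
  )

  structure(
    list(
      treatment_phase = list(
        metrics = metrics,
        group_means = dplyr::summarise(
          excl$retained,
          go_rt_ms = mean(.data$go_rt_ms),
          failed_stop_rt_ms = mean(.data$failed_stop_rt_ms),
          p_stop = mean(.data$p_stop),
          mean_ssd_ms = mean(.data$mean_ssd_ms),
          ssrt_ms = mean(.data$ssrt_ms),
          miss_rate = mean(.data$miss_rate),
          error_rate = mean(.data$error_rate)
        ),
        race_validity = race,
        exclusions = excl$excluded[, c("participant", "reason")],
        n_retained = length(kept_ids)
      ),
      types_of_knowledge = list(
        classification = knowledge,
        n_explicit = sum(knowledge$knowledge == "explicit"),
        n_implicit = sum(knowledge$knowledge == "implicit")
      ),
      valuation_phase = list(
        devaluation_scores = scores,
        outliers_removed = outlier_ids,
        n_analysis = length(analysis_ids),
        anova = main_anova,
        cell_means = dplyr::summarise(
          dplyr::group_by(cells_kept, .data$knowledge, .data$stopping,
                          .data$value_level),
          mean_bid_level = mean(.data$mean_bid_level), .groups = "drop"
        )
      ),
      within_subjects = within_subj,
      control_analyses = list(stopping_wilcoxon = wilcoxon,
                              knowledge_stopping_mann_whitney = mw),
      bidding_variance = variance,
      implicit_learners = list(anova = implicit_anova,
                               variance_correlation = implicit_corr)
    ),
    class = "devalsim_report"
  )
}

#' @export
print.devalsim_report <- function(x, ...) {
  tp <- x$treatment_phase
  cat("== Treatment phase ==\n")
  gm <- tp$group_means
  cat(sprintf("  n = %d retained (%d excluded); GoRT %.0f ms, failed-stop RT %.0f ms,\n",
              tp$n_retained, nrow(tp$exclusions), gm$go_rt_ms,
              gm$failed_stop_rt_ms))
  cat(sprintf("  p(stop) %.3f, SSD %.0f ms, SSRT %.0f ms\n", gm$p_stop,
              gm$mean_ssd_ms, gm$ssrt_ms))
  cat("  race validity: "); print(tp$race_validity$test)
  tk <- x$types_of_knowledge
  cat(sprintf("== Knowledge == %d explicit / %d implicit\n",
              tk$n_explicit, tk$n_implicit))
  vp <- x$valuation_phase
  cat(sprintf("== Valuation phase == %d analyzed (%d IQR outliers removed)\n",
              vp$n_analysis, length(vp$outliers_removed)))
  tab <- vp$anova
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s F(%d,%d) = %6.2f, p = %.4g, pes = %.3f\n",
                tab$effect[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i],
                tab$partial_eta_sq[i]))
  }
  cat("== Control analyses ==\n")
  cat("  stop vs go bids (Wilcoxon): ")
  print(x$control_analyses$stopping_wilcoxon)
  if (!is.null(x$control_analyses$knowledge_stopping_mann_whitney)) {
    cat("  devaluation by group (Mann-Whitney): ")
    print(x$control_analyses$knowledge_stopping_mann_whitney)
  }
  if (!is.null(x$within_subjects)) {
    cat(sprintf("== Within-subjects (n = %d) == explicit vs implicit pairs: ",
                x$within_subjects$n))
    print(x$within_subjects$paired_test)
  }
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Command-style wrapper binding [simulate_cohort()] to the documented
#' file layout.
#'
#' @param out_dir Output directory.
#' @param n_agents Number of participants.
#' @param preset Preset name for [cohort_preset()], ignored when
#'   `config` is given.
#' @param config Optional `study_config` or path to a config JSON/YAML.
#' @param seed Integer seed.
#' @param population A `population_params`.
#' @return The manifest, invisibly.
#' @export
cmd_simulate <- function(out_dir, n_agents = 65, preset = "cohortB",
                         config = NULL, seed = 1,
                         population = population_params()) {
  cfg <- resolve_config(config, preset)
  dataset <- simulate_cohort(n_agents, cfg, population, rng_seed = seed)
  write_dataset(dataset, out_dir)
}

#' Analyze a dataset directory and write the stats report
#'
#' Reads a dataset written by [cmd_simulate()]/[write_dataset()], runs
#' [analyze_study()], and writes `report.json` (all test results) plus
#' `anova.csv`, `stop_metrics.csv` and `devaluation_scores.csv` under
#' `out_dir`.
#'
#' @param dataset_dir Directory holding the dataset.
#' @param out_dir Output directory (defaults to `dataset_dir`).
#' @return The report, invisibly.
#' @export
cmd_analyze <- function(dataset_dir, out_dir = dataset_dir) {
  dataset <- read_dataset(dataset_dir)
  report <- analyze_study(dataset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(report$valuation_phase$anova, file.path(out_dir, "anova.csv"))
  write_trials(report$treatment_phase$metrics,
               file.path(out_dir, "stop_metrics.csv"))
  write_trials(report$valuation_phase$devaluation_scores,
               file.path(out_dir, "devaluation_scores.csv"))
  jsonlite::write_json(report_to_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' End-to-end demonstration run
#'
#' Simulates a default 65-participant cohort (22 explicit learners) with
#' the documented default effect sizes, analyzes it, and prints the
#' report including the group x stopping x value cell means.
#'
#' @param seed Integer seed.
#' @param n_agents Cohort size.
#' @param quiet Suppress printing.
#' @return The `devalsim_report`, invisibly.
#' @export
cmd_replicate <- function(seed = 1, n_agents = 65, quiet = FALSE) {
  dataset <- simulate_cohort(n_agents, cohort_preset("cohortB"),
                             population_params(), rng_seed = seed)
  report <- analyze_study(dataset)
  if (!quiet) {
    print(report)
    cat("== Cell means (bid level 1-6) ==\n")
    print(as.data.frame(report$valuation_phase$cell_means))
  }
  invisible(report)
}

#' Emit trial schedules only
#'
#' Generates one participant's stimulus assignment and all three phase
#' schedules, written as CSV.
#'
#' @param out_dir Output directory.
#' @param preset,config,seed As in [cmd_simulate()].
#' @return Invisibly, the list of written paths.
#' @export
cmd_schedules <- function(out_dir, preset = "cohortB", config = NULL,
                          seed = 1) {
  cfg <- resolve_config(config, preset)
  withr::with_seed(as.integer(seed), {
    stimuli <- assign_stimuli(cfg)
    paths <- c(
      write_trials(stimuli, file.path(out_dir, "stimuli.csv")),
      write_trials(generate_learning_schedule(cfg, stimuli),
                   file.path(out_dir, "learning_schedule.csv")),
      write_trials(generate_treatment_schedule(cfg, stimuli),
                   file.path(out_dir, "treatment_schedule.csv")),
      write_trials(generate_auction_schedule(cfg, stimuli),
                   file.path(out_dir, "auction_schedule.csv"))
    )
  })
  invisible(paths)
}

resolve_config <- function(config, preset) {
  if (is.null(config)) return(cohort_preset(preset))
  if (inherits(config, "study_config")) return(config)
  read_config(config)
}

# Flatten a report into JSON-friendly structures (stat_result -> plain list).
report_to_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "stat_result")) return(unclass(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(report))
}
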