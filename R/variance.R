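#' Bidding-level variance analyses
#'
#' Treats the per-shape *variance* of bidding levels as the dependent
#' variable: lower variance indicates more consistent bids, a behavioral
#' proxy for stronger value knowledge. Runs the same 2 x 2 x 4 mixed ANOVA
#' as the mean-bid analysis with `bid_level_variance` as DV, and, within
#' explicit learners, a paired t-test of mean variance on accurately named
#' shapes vs the remaining shapes (participants with no or only named
#' shapes drop from the paired part).
#'
#' @param dataset A `devalsim_dataset`.
#' @param knowledge Classification tibble (recomputed when `NULL`).
#' @param participants Optional participant ids to restrict to (e.g. the
#'   outlier-filtered analysis sample).
#' @return `list(anova, named_vs_unnamed, per_participant)`.
#' @export
bidding_variance_analysis <- function(dataset, knowledge = NULL,
                                      participants = NULL) {
  if (is.null(knowledge)) knowledge <- classify_cohort_knowledge(dataset)
  cells <- bid_cell_summaries(dataset$auction, dataset$config, knowledge)
  if (!is.null(participants)) {
    cells <- cells[cells$participant %in% participants, ]
  }
  anova_tab <- mixed_anova_2x2x4(cells, dv = "bid_level_variance")

  explicit_ids <- intersect(
    knowledge$participant[knowledge$knowledge == "explicit"],
    unique(cells$participant)
  )
  rows <- list()
  for (pid in explicit_ids) {
    stim <- dataset$stimuli[dataset$stimuli$participant == pid, ]
    named <- correctly_named_shapes(dataset$debriefs[[pid]], stim)
    d <- cells[cells$participant == pid, ]
    is_named <- d$stimulus_id %in% named
    if (!any(is_named) || all(is_named)) next
    rows[[pid]] <- tibble::tibble(
      participant = pid,
      named_variance = mean(d$bid_level_variance[is_named]),
      unnamed_variance = mean(d$bid_level_variance[!is_named])
    )
  }
  named_vs_unnamed <- NULL
  per <- dplyr::bind_rows(rows)
  if (nrow(per) >= 3L) {
    diffs <- per$unnamed_variance - per$named_variance
    tt <- stats::t.test(diffs)
    named_vs_unnamed <- stat_result(
      statistic = "t", value = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      effect_size = mean(diffs) / stats::sd(diffs),
      effect_size_type = "cohen_d",
      effect_size_formula = "d_z = mean(diff)/sd(diff)"
    )
  }
  list(anova = anova_tab, named_vs_unnamed = named_vs_unnamed,
       per_participant = per)
}

#' Implicit learners: bidding variance vs devaluation
#'
#' For implicit learners only, builds a compound knowledge proxy — the
#' mean per-shape bid-level variance over the four extreme-value shapes
#' (both shapes of the lowest and highest value levels, where differential
#' value is most salient) — and correlates it with the devaluation score,
#' after removing points with Cook's distance above `4/N` in the simple
#' regression of score on the compound measure. A negative correlation
#' means lower-variance (more knowledgeable) implicit learners devalue
#' more.
#'
#' @param dataset A `devalsim_dataset`.
#' @param knowledge Classification tibble (recomputed when `NULL`).
#' @param levels Value levels treated as extreme (default lowest, highest).
#' @return `list(test, data, removed)` as in
#'   [cooks_filtered_correlation()], with `data` holding the per-
#'   participant compound measure and score.
#' @export
implicit_variance_devaluation_correlation <- function(dataset,
                                                      knowledge = NULL,
                                                      levels = c(1L, 4L)) {
  if (is.null(knowledge)) knowledge <- classify_cohort_knowledge(dataset)
  implicit_ids <- knowledge$participant[knowledge$knowledge == "implicit"]
  if (length(implicit_ids) < 10L) {
    stop("need at least 10 implicit learners", call. = FALSE)
  }
  cells <- bid_cell_summaries(dataset$auction, dataset$config)
  cells <- cells[cells$participant %in% implicit_ids &
                   cells$value_level %in% levels, ]
  compound <- dplyr::summarise(
    dplyr::group_by(cells, .data$participant),
    compound_variance = mean(.data$bid_level_variance), .groups = "drop"
  )
  scores <- devaluation_scores(dataset$auction, dataset$config)
  d <- dplyr::inner_join(compound, scores, by = "participant")
  res <- cooks_filtered_correlation(d$compound_variance,
                                    d$devaluation_score)
  list(test = res$test, data = d,
       removed = d$participant[res$removed])
}
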