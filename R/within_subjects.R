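#' Within-subject contrast of devaluation for explicitly vs implicitly
#' represented shape pairs
#'
#' Restricted to explicit learners. Each of the four equal-value shape
#' pairs (one stop-paired, one never-stopped shape) is classified as an
#' *explicit pair* if the value of at least one of its two shapes was
#' accurately named in the debrief, and an *implicit pair* otherwise. Per
#' pair, devaluation is expressed as the percent bidding-level reduction
#' on the stop-paired shape relative to its never-stopped partner,
#' `100 * (L_go - L_stop) / L_go`. Within a participant, the median is
#' taken across the qualifying pairs of each condition; participants whose
#' four pairs all fall in one condition are excluded. The two conditions
#' are compared with a paired t-test (one-sided: explicit pairs show more
#' devaluation), alongside per-condition one-sample t-tests against zero.
#'
#' @param dataset A `devalsim_dataset`.
#' @param knowledge Classification tibble from
#'   [classify_cohort_knowledge()] (recomputed when `NULL`).
#' @return `list(per_participant, paired_test, explicit_vs_zero,
#'   implicit_vs_zero, n)`; `per_participant` holds the two condition
#'   medians per retained participant.
#' @export
within_subjects_pair_analysis <- function(dataset, knowledge = NULL) {
  if (is.null(knowledge)) knowledge <- classify_cohort_knowledge(dataset)
  explicit_ids <- knowledge$participant[knowledge$knowledge == "explicit"]
  if (!length(explicit_ids)) stop("no explicit learners", call. = FALSE)
  cells <- bid_cell_summaries(dataset$auction, dataset$config)
  rows <- list()
  for (pid in explicit_ids) {
    stim <- dataset$stimuli[dataset$stimuli$participant == pid, ]
    named <- correctly_named_shapes(dataset$debriefs[[pid]], stim)
    d <- cells[cells$participant == pid, ]
    pct <- numeric(0)
    cond <- logical(0)
    for (lv in sort(unique(d$value_level))) {
      pair <- d[d$value_level == lv, ]
      l_go <- pair$mean_bid_level[pair$stopping == "go"]
      l_stop <- pair$mean_bid_level[pair$stopping == "stop"]
      pair_ids <- stim$stimulus_id[stim$value_level == lv]
      is_explicit_pair <- any(pair_ids %in% named)
      pct <- c(pct, 100 * (l_go - l_stop) / l_go)
      cond <- c(cond, is_explicit_pair)
    }
    if (all(cond) || !any(cond)) next  # single-condition participants drop
    rows[[pid]] <- tibble::tibble(
      participant = pid,
      explicit_pair_pct = stats::median(pct[cond]),
      implicit_pair_pct = stats::median(pct[!cond])
    )
  }
  if (length(rows) < 2L) {
    stop("fewer than two eligible explicit learners", call. = FALSE)
  }
  per <- dplyr::bind_rows(rows)
  diffs <- per$explicit_pair_pct - per$implicit_pair_pct
  tt <- stats::t.test(diffs, alternative = "greater")
  paired_test <- stat_result(
    statistic = "t", value = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value,
    effect_size = mean(diffs) / stats::sd(diffs),
    effect_size_type = "cohen_d",
    effect_size_formula = "d_z = mean(diff)/sd(diff)",
    alternative = "greater"
  )
  one_sample <- function(v) {
    tt <- stats::t.test(v)
    stat_result(statistic = "t", value = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                effect_size = mean(v) / stats::sd(v),
                effect_size_type = "cohen_d",
                effect_size_formula = "d_z = mean/sd")
  }
  list(
    per_participant = per,
    paired_test = paired_test,
    explicit_vs_zero = one_sample(per$explicit_pair_pct),
    implicit_vs_zero = one_sample(per$implicit_pair_pct),
    n = nrow(per)
  )
}

# Stimulus ids whose claimed value level matches the true level.
correctly_named_shapes <- function(debrief, stimuli) {
  named <- debrief$named_shapes
  if (is.null(named) || nrow(named) == 0L) return(character())
  true_level <- stimuli$value_level[match(named$stimulus_id,
                                          stimuli$stimulus_id)]
  named$stimulus_id[!is.na(true_level) &
                      named$claimed_value_level == true_level]
}
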