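#' Convert chosen amounts to bidding levels
#'
#' The valuation dependent variable is the rank (1-6, lowest to highest)
#' of the chosen amount within that trial's bid set, which makes bids
#' comparable across the five differently scaled sets and independent of
#' the on-screen key assignment.
#'
#' @param chosen_amount Vector of chosen amounts (cents).
#' @param bid_set A strictly increasing 6-vector, or (vectorized use) a
#'   list of such sets, one per element of `chosen_amount`.
#' @return Integer vector of levels in 1-6.
#' @export
bid_to_level <- function(chosen_amount, bid_set) {
  sets <- if (is.list(bid_set)) bid_set else list(bid_set)
  if (length(sets) == 1L) sets <- rep(sets, length(chosen_amount))
  stopifnot(length(sets) == length(chosen_amount))
  vapply(seq_along(chosen_amount), function(i) {
    set <- sets[[i]]
    stopifnot(length(set) == 6L, all(diff(set) > 0))
    lv <- match(chosen_amount[i], set)
    if (is.na(lv)) {
      stop("amount ", chosen_amount[i], " is not in the bid set",
           call. = FALSE)
    }
    lv
  }, integer(1))
}

#' Attach bidding levels to an auction log
#'
#' @param auction_log Auction log with `bid_set_id` and
#'   `chosen_amount_cents`.
#' @param config The `study_config` supplying the bid sets.
#' @return The log with a `bid_level` column.
#' @export
auction_bid_levels <- function(auction_log, config) {
  auction_log$bid_level <- bid_to_level(
    auction_log$chosen_amount_cents,
    config$bid_sets[auction_log$bid_set_id]
  )
  auction_log
}

#' Classify a participant as explicit or implicit learner
#'
#' Explicit requires both a reported feeling of knowing about the reward
#' regularity and at least one *accurately* named shape (the claimed value
#' level matches the shape's true level); anything else is implicit.
#'
#' @param debrief A `simulated_debrief` (or equivalent list).
#' @param stimuli The participant's stimulus table (true value levels).
#' @return `"explicit"` or `"implicit"`.
#' @export
classify_knowledge <- function(debrief, stimuli) {
  if (!isTRUE(debrief$reported_contingency_feeling)) return("implicit")
  named <- debrief$named_shapes
  if (is.null(named) || nrow(named) == 0L) return("implicit")
  true_level <- stimuli$value_level[match(named$stimulus_id,
                                          stimuli$stimulus_id)]
  any_correct <- any(!is.na(true_level) &
                       named$claimed_value_level == true_level)
  if (any_correct) "explicit" else "implicit"
}

#' Classify every participant in a dataset
#'
#' @param dataset A `devalsim_dataset`.
#' @return Tibble with `participant` and `knowledge` columns.
#' @export
classify_cohort_knowledge <- function(dataset) {
  parts <- names(dataset$debriefs)
  knowledge <- vapply(parts, function(pid) {
    stim <- dataset$stimuli[dataset$stimuli$participant == pid, ]
    classify_knowledge(dataset$debriefs[[pid]], stim)
  }, character(1))
  tibble::tibble(participant = parts, knowledge = unname(knowledge))
}

#' Per-participant cell summaries of bidding level
#'
#' Aggregates the auction log into the ANOVA's dependent variables: for
#' every participant and STOPPING x VALUE cell (one shape per cell), the
#' mean and the sample variance of its bid levels.
#'
#' @param auction_log Cohort auction log (with `participant`).
#' @param config The `study_config`.
#' @param knowledge Optional tibble (`participant`, `knowledge`) to join.
#' @return Tibble with columns `participant`, `knowledge` (if supplied),
#'   `stopping` (`"stop"`/`"go"`), `value_level`, `stimulus_id`,
#'   `mean_bid_level`, `bid_level_variance`, `n_bids`.
#' @export
bid_cell_summaries <- function(auction_log, config, knowledge = NULL) {
  log <- auction_bid_levels(auction_log, config)
  out <- dplyr::summarise(
    dplyr::group_by(log, .data$participant, .data$stop_paired,
                    .data$value_level, .data$stimulus_id),
    mean_bid_level = mean(.data$bid_level),
    bid_level_variance = stats::var(.data$bid_level),
    n_bids = dplyr::n(),
    .groups = "drop"
  )
  out$stopping <- ifelse(out$stop_paired, "stop", "go")
  out$stop_paired <- NULL
  if (!is.null(knowledge)) {
    out <- dplyr::left_join(out, knowledge, by = "participant")
  }
  out[, c("participant", intersect("knowledge", names(out)), "stopping",
          "value_level", "stimulus_id", "mean_bid_level",
          "bid_level_variance", "n_bids")]
}

#' Per-participant devaluation scores
#'
#' Mean bid level over the four never-stopped shapes minus the mean over
#' the four stop-paired shapes; positive values indicate stopping-induced
#' devaluation.
#'
#' @param auction_log Cohort auction log.
#' @param config The `study_config`.
#' @return Tibble with `participant` and `devaluation_score`.
#' @export
devaluation_scores <- function(auction_log, config) {
  cells <- bid_cell_summaries(auction_log, config)
  per <- split(cells, cells$participant)
  rows <- lapply(per, function(d) {
    if (!all(table(d$stopping) == 4L)) {
      stop("participant ", d$participant[1],
           " lacks complete shape coverage", call. = FALSE)
    }
    tibble::tibble(
      participant = d$participant[1],
      devaluation_score = mean(d$mean_bid_level[d$stopping == "go"]) -
        mean(d$mean_bid_level[d$stopping == "stop"])
    )
  })
  dplyr::bind_rows(rows)
}

#' Interquartile-range outlier filter, by group
#'
#' Removes values outside `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles
#' computed separately within each group by linear-interpolation quantiles
#' (`type = 7` by default; the method is exposed because conventions
#' differ). Groups smaller than `min_group` are passed through untouched
#' with a warning.
#'
#' @param scores Numeric vector.
#' @param groups Group labels, same length as `scores`.
#' @param k IQR multiplier (1.5 by default).
#' @param qtype Quantile algorithm passed to [stats::quantile()].
#' @param min_group Minimum group size for filtering.
#' @return `list(retained, removed)`: logical `retained` mask aligned with
#'   `scores`, and the indices removed.
#' @export
iqr_outlier_filter <- function(scores, groups = rep("all", length(scores)),
                               k = 1.5, qtype = 7, min_group = 4L) {
  stopifnot(length(scores) == length(groups))
  keep <- rep(TRUE, length(scores))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < min_group) {
      warning("group '", g, "' has fewer than ", min_group,
              " members; no outlier filtering applied")
      next
    }
    q <- stats::quantile(scores[idx], c(0.25, 0.75), type = qtype,
                         names = FALSE)
    iqr <- q[2] - q[1]
    keep[idx] <- scores[idx] >= q[1] - k * iqr & scores[idx] <= q[2] + k * iqr
  }
  list(retained = keep, removed = which(!keep))
}
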