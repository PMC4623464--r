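#' Per-participant stop-signal task metrics
#'
#' Computes the standard race-model summary of one treatment-phase log:
#' mean correct go RT (misses and direction errors excluded), mean failed-
#' stop RT, the proportion of successful stops, the mean presented SSD
#' (pooled over hands, with per-hand diagnostics), and the mean-method SSRT
#' estimate `go_rt - mean_ssd`. Miss and error rates are computed over go
#' trials.
#'
#' @param treatment_log One participant's treatment log (columns
#'   `is_stop_trial`, `side`, `ssd_ms`, `outcome`, `rt_ms`).
#' @return A one-row tibble of class fields: `go_rt_ms`,
#'   `failed_stop_rt_ms`, `p_stop`, `mean_ssd_ms`, `mean_ssd_left_ms`,
#'   `mean_ssd_right_ms`, `ssrt_ms`, `miss_rate`, `error_rate`,
#'   `race_valid` (failed-stop RT strictly below go RT; `NA` without failed
#'   stops), and counts.
#' @export
compute_stop_metrics <- function(treatment_log) {
  go <- treatment_log[!treatment_log$is_stop_trial, ]
  stop_trials <- treatment_log[treatment_log$is_stop_trial, ]
  if (nrow(go) == 0L || nrow(stop_trials) == 0L) {
    stop("stop metrics need at least one go and one stop trial",
         call. = FALSE)
  }
  go_rt <- mean(go$rt_ms[go$outcome == "go_correct"])
  failed <- stop_trials$rt_ms[stop_trials$outcome == "failed_stop"]
  failed_rt <- if (length(failed)) mean(failed) else NA_real_
  mean_ssd <- mean(stop_trials$ssd_ms)
  ssd_side <- tapply(stop_trials$ssd_ms, stop_trials$side, mean)
  tibble::tibble(
    n_go = nrow(go),
    n_stop = nrow(stop_trials),
    go_rt_ms = go_rt,
    failed_stop_rt_ms = failed_rt,
    p_stop = mean(stop_trials$outcome == "successful_stop"),
    mean_ssd_ms = mean_ssd,
    mean_ssd_left_ms = unname(ssd_side["left"]),
    mean_ssd_right_ms = unname(ssd_side["right"]),
    ssrt_ms = go_rt - mean_ssd,
    miss_rate = mean(go$outcome == "go_miss"),
    error_rate = mean(go$outcome == "go_error"),
    race_valid = if (length(failed)) failed_rt < go_rt else NA
  )
}

#' Stop metrics for every participant in a cohort log
#'
#' @param treatment_log Treatment log with a `participant` column.
#' @return A tibble, one row per participant, as in
#'   [compute_stop_metrics()].
#' @export
stop_metrics_by_participant <- function(treatment_log) {
  parts <- split(treatment_log, treatment_log$participant)
  out <- dplyr::bind_rows(lapply(parts, compute_stop_metrics))
  tibble::add_column(out, participant = names(parts), .before = 1)
}

#' Race-model validity check
#'
#' Flags each participant by whether mean failed-stop RT is strictly below
#' mean go RT (the signature of an independent race, where failed stops
#' over-sample the fast tail of the go distribution), and tests the
#' difference at cohort level with a paired t-test (`go - failed`, df =
#' participants - 1) with Cohen's `d_z`.
#'
#' @param treatment_log Cohort treatment log with a `participant` column,
#'   or a precomputed metrics table from [stop_metrics_by_participant()].
#' @return `list(per_participant, test)`: flags per participant (`NA` where
#'   no failed stops occurred) and a `stat_result` for the cohort test.
#' @export
check_race_validity <- function(treatment_log) {
  metrics <- if ("is_stop_trial" %in% names(treatment_log)) {
    stop_metrics_by_participant(treatment_log)
  } else {
    treatment_log
  }
  usable <- !is.na(metrics$failed_stop_rt_ms)
  if (!any(usable)) {
    stop("no participant has any failed stop trial", call. = FALSE)
  }
  diffs <- metrics$go_rt_ms[usable] - metrics$failed_stop_rt_ms[usable]
  tt <- stats::t.test(diffs)
  test <- stat_result(
    statistic = "t", value = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value,
    effect_size = mean(diffs) / stats::sd(diffs),
    effect_size_type = "cohen_d", effect_size_formula = "d_z = mean(diff)/sd(diff)"
  )
  list(
    per_participant = tibble::tibble(
      participant = metrics$participant,
      race_valid = metrics$race_valid
    ),
    test = test
  )
}

#' Apply stop-task participant exclusions
#'
#' Removes participants whose stopping behavior is outside the usable
#' range: probability of stopping outside `p_stop_bounds` (the tracking
#' staircase should hold it near 0.5), SSRT outside `ssrt_bounds`
#' (plausible range for manual stopping with auditory signals), or a
#' violated race model (failed-stop RT not faster than go RT) when
#' `require_race_valid`.
#'
#' @param metrics Metrics table from [stop_metrics_by_participant()].
#' @param p_stop_bounds,ssrt_bounds Inclusive bounds.
#' @param require_race_valid Exclude race-model violations.
#' @return `list(retained, excluded)`; `excluded` carries a `reason` column
#'   with comma-joined reason codes (`p_stop`, `ssrt`, `race_model`).
#' @export
apply_exclusions <- function(metrics,
                             p_stop_bounds = c(0.4, 0.6),
                             ssrt_bounds = c(120, 300),
                             require_race_valid = TRUE) {
  reasons <- vapply(seq_len(nrow(metrics)), function(i) {
    r <- character()
    if (metrics$p_stop[i] < p_stop_bounds[1] ||
        metrics$p_stop[i] > p_stop_bounds[2]) r <- c(r, "p_stop")
    if (metrics$ssrt_ms[i] < ssrt_bounds[1] ||
        metrics$ssrt_ms[i] > ssrt_bounds[2]) r <- c(r, "ssrt")
    if (require_race_valid && isFALSE(metrics$race_valid[i])) {
      r <- c(r, "race_model")
    }
    paste(r, collapse = ",")
  }, character(1))
  keep <- reasons == ""
  excluded <- metrics[!keep, , drop = FALSE]
  excluded$reason <- reasons[!keep]
  list(retained = metrics[keep, , drop = FALSE], excluded = excluded)
}

#' Per-block monitoring report
#'
#' Reproduces the experimenter's between-block checks as warnings rather
#' than exclusions: go RT should sit in `go_rt_bounds`, p(stop) in
#' `p_stop_bounds`, and SSD above `ssd_min_ms` in every block.
#'
#' @param treatment_log One participant's treatment log.
#' @param go_rt_bounds,p_stop_bounds,ssd_min_ms Monitoring targets.
#' @return A tibble with one row per block: the block metrics and a
#'   comma-joined `warnings` column (empty when all targets are met).
#' @export
monitor_blocks <- function(treatment_log, go_rt_bounds = c(400, 650),
                           p_stop_bounds = c(0.4, 0.6), ssd_min_ms = 100) {
  blocks <- split(treatment_log, treatment_log$block)
  rows <- lapply(blocks, function(b) {
    go <- b[!b$is_stop_trial & b$outcome == "go_correct", ]
    st <- b[b$is_stop_trial, ]
    go_rt <- if (nrow(go)) mean(go$rt_ms) else NA_real_
    p_stop <- if (nrow(st)) mean(st$outcome == "successful_stop") else NA_real_
    ssd <- if (nrow(st)) mean(st$ssd_ms) else NA_real_
    warn <- character()
    if (!is.na(go_rt) && (go_rt < go_rt_bounds[1] || go_rt > go_rt_bounds[2])) {
      warn <- c(warn, "go_rt")
    }
    if (!is.na(p_stop) &&
        (p_stop < p_stop_bounds[1] || p_stop > p_stop_bounds[2])) {
      warn <- c(warn, "p_stop")
    }
    if (!is.na(ssd) && ssd <= ssd_min_ms) warn <- c(warn, "ssd")
    tibble::tibble(block = b$block[1], go_rt_ms = go_rt, p_stop = p_stop,
                   mean_ssd_ms = ssd, warnings = paste(warn, collapse = ","))
  })
  dplyr::bind_rows(rows)
}
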