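#' Construct a simulated participant
#'
#' An agent couples a horse-race motor model (independent ex-Gaussian go
#' and stop processes) with a knowledge-dependent valuation model. Its
#' true stop-signal reaction time is the mean of the stop-latency
#' distribution (`mu + tau`), which the mean-method estimator should
#' recover from treatment-phase logs.
#'
#' Valuation: after learning, the agent carries a per-shape internal value
#' estimate (the running mean of the non-zero rewards it observed). In the
#' auction its subjective worth of a shape is
#' `value_sensitivity * internal_value * (1 - devaluation)`, plus Gaussian
#' bid noise; `devaluation` applies only to stop-paired shapes and is
#' larger for shapes whose value the agent can explicitly name
#' (`devaluation_effect["known"]` vs `["unknown"]`). Bid noise is likewise
#' smaller for explicitly known shapes.
#'
#' @param knowledge `"explicit"` or `"implicit"`.
#' @param go_rt Named vector `c(mu, sigma, tau)` of the go-RT ex-Gaussian,
#'   in ms.
#' @param stop_latency Named vector `c(mu, sigma, tau)` of the stop-latency
#'   ex-Gaussian, in ms; its mean is the agent's true SSRT.
#' @param miss_rate Probability of failing to emit a go response.
#' @param error_rate Probability of a direction/quadrant error.
#' @param known_value_shapes Character vector of stimulus ids whose trained
#'   value the agent can name (non-empty for explicit agents).
#' @param value_sensitivity Slope of subjective worth per trained cent.
#' @param bid_noise_sd Named vector `c(known, unknown)`: SD of bid noise in
#'   cents for explicitly known vs other shapes.
#' @param devaluation_effect Named vector `c(known, unknown)`: proportional
#'   worth reduction for stop-paired shapes, by knowledge of the shape.
#' @param stop_contingency_aware Did the agent notice which shapes carried
#'   stop signals (debrief bookkeeping only).
#' @param rng_seed Optional integer seed used by the phase simulators.
#'
#' @return A list of class `agent_profile`.
#' @export
agent_profile <- function(knowledge = c("implicit", "explicit"),
                          go_rt = c(mu = 400, sigma = 40, tau = 70),
                          stop_latency = c(mu = 150, sigma = 20, tau = 40),
                          miss_rate = 0.006,
                          error_rate = 0.002,
                          known_value_shapes = character(),
                          value_sensitivity = 1,
                          bid_noise_sd = c(known = 25, unknown = 60),
                          devaluation_effect = c(known = 0.05, unknown = 0.05),
                          stop_contingency_aware = FALSE,
                          rng_seed = NULL) {
  knowledge <- match.arg(knowledge)
  stopifnot(
    all(c("mu", "sigma", "tau") %in% names(go_rt)),
    all(c("mu", "sigma", "tau") %in% names(stop_latency)),
    go_rt[["sigma"]] > 0, go_rt[["tau"]] > 0,
    stop_latency[["sigma"]] > 0, stop_latency[["tau"]] > 0,
    miss_rate >= 0, miss_rate <= 1, error_rate >= 0, error_rate <= 1,
    all(c("known", "unknown") %in% names(bid_noise_sd)),
    all(bid_noise_sd >= 0),
    all(c("known", "unknown") %in% names(devaluation_effect)),
    all(devaluation_effect >= 0), all(devaluation_effect < 1),
    value_sensitivity > 0
  )
  structure(
    list(
      knowledge = knowledge,
      go_rt = go_rt,
      stop_latency = stop_latency,
      miss_rate = miss_rate,
      error_rate = error_rate,
      known_value_shapes = known_value_shapes,
      value_sensitivity = value_sensitivity,
      bid_noise_sd = bid_noise_sd,
      devaluation_effect = devaluation_effect,
      stop_contingency_aware = stop_contingency_aware,
      rng_seed = if (!is.null(rng_seed)) as.integer(rng_seed),
      value_estimates = NULL
    ),
    class = "agent_profile"
  )
}

#' True mean stop latency (SSRT) of an agent
#' @param agent An `agent_profile`.
#' @return Scalar ms.
#' @export
true_ssrt <- function(agent) {
  unname(agent$stop_latency[["mu"]] + agent$stop_latency[["tau"]])
}

#' Resolve one trial of the independent horse race
#'
#' On a stop trial the response is cancelled iff the stop process finishes
#' no later than the go process (`ssd + stop_latency <= go_rt`; ties count
#' as successful stops). A go process that has not finished by the deadline
#' produces no overt response (a miss on go trials; an apparent successful
#' stop on stop trials). Failed stops report the go RT.
#'
#' @param go_rt_sample Go-process finishing time (ms), `Inf` for a lapse.
#' @param stop_latency_sample Stop-process duration (ms); ignored on go
#'   trials.
#' @param ssd Stop-signal delay (ms), or `NA` for a go trial.
#' @param deadline_ms Response deadline (ms).
#' @return `list(outcome, rt_ms)` with outcome one of `"go_response"`,
#'   `"go_miss"`, `"successful_stop"`, `"failed_stop"`.
#' @export
race_trial <- function(go_rt_sample, stop_latency_sample = NA_real_,
                       ssd = NA_real_, deadline_ms = 1000) {
  stopifnot(is.na(ssd) || ssd >= 0, go_rt_sample >= 0,
            is.na(stop_latency_sample) || stop_latency_sample >= 0)
  go_time <- if (go_rt_sample > deadline_ms) Inf else go_rt_sample
  if (is.na(ssd)) {
    if (is.infinite(go_time)) {
      list(outcome = "go_miss", rt_ms = NA_real_)
    } else {
      list(outcome = "go_response", rt_ms = go_rt_sample)
    }
  } else {
    if (ssd + stop_latency_sample <= go_time) {
      list(outcome = "successful_stop", rt_ms = NA_real_)
    } else {
      list(outcome = "failed_stop", rt_ms = go_rt_sample)
    }
  }
}

#' Update the per-hand SSD staircase
#'
#' The stop-signal delay for the responding hand moves up by `step_ms`
#' after a successful stop (making stopping harder) and down by `step_ms`
#' after a failed stop, clamped to `[floor_ms, ceiling_ms]`; the other
#' hand's delay is untouched. This one-up/one-down rule tracks the 50%
#' stopping success point.
#'
#' @param state Named numeric `c(left=, right=)` of current SSDs (ms).
#' @param side `"left"` or `"right"`.
#' @param outcome `"successful_stop"` or `"failed_stop"`.
#' @param step_ms,floor_ms,ceiling_ms Staircase parameters.
#' @return The updated state vector.
#' @export
staircase_update <- function(state, side, outcome, step_ms = 50,
                             floor_ms = 0, ceiling_ms = 1000) {
  stopifnot(all(c("left", "right") %in% names(state)),
            side %in% c("left", "right"))
  if (!outcome %in% c("successful_stop", "failed_stop")) {
    stop("staircase_update() requires a stop-trial outcome, got ",
         outcome, call. = FALSE)
  }
  delta <- if (outcome == "successful_stop") step_ms else -step_ms
  state[[side]] <- min(max(state[[side]] + delta, floor_ms), ceiling_ms)
  state
}

#' Simulate the learning phase for one agent
#'
#' Every scheduled trial is eventually completed correctly; trials on which
#' the agent missed the deadline or pressed the wrong key are repeated
#' until correct, and the number of presentations is recorded in
#' `presented_repeats`. The agent's internal value estimate for each shape
#' is the mean of the non-zero rewards it observed (zero-reward trials are
#' treated as omissions, not evidence about the shape's worth).
#'
#' @param agent An `agent_profile`.
#' @param schedule Learning schedule from [generate_learning_schedule()].
#' @param config The `study_config` (for the response deadline).
#' @param rng_seed Optional seed (defaults to the agent's own).
#' @return `list(log, agent)`: the completed-trial log (one row per
#'   scheduled trial, with `rt_ms`, `correct`, `presented_repeats`) and the
#'   agent carrying `value_estimates`.
#' @export
simulate_learning_phase <- function(agent, schedule, config = cohort_preset(),
                                    rng_seed = agent$rng_seed) {
  stopifnot(inherits(agent, "agent_profile"))
  n <- nrow(schedule)
  with_seed_if(rng_seed, {
    fail_p <- min(agent$miss_rate + agent$error_rate, 0.99)
    repeats <- if (n) stats::rgeom(n, prob = 1 - fail_p) + 1L else integer()
    rt <- rexgauss(n, agent$go_rt[["mu"]], agent$go_rt[["sigma"]],
                   agent$go_rt[["tau"]])
    # the completed (correct) response necessarily beat the deadline
    over <- which(rt > config$response_deadline_ms)
    while (length(over)) {
      rt[over] <- rexgauss(length(over), agent$go_rt[["mu"]],
                           agent$go_rt[["sigma"]], agent$go_rt[["tau"]])
      over <- over[rt[over] > config$response_deadline_ms]
    }
    log <- schedule
    log$rt_ms <- round(rt, 1)
    log$correct <- TRUE
    log$presented_repeats <- as.integer(repeats)
    rewarded <- log$scheduled_reward_cents > 0
    est <- tapply(log$scheduled_reward_cents[rewarded],
                  log$stimulus_id[rewarded], mean)
    agent$value_estimates <- stats::setNames(as.numeric(est), names(est))
    list(log = tibble::as_tibble(log), agent = agent)
  })
}

#' Simulate the treatment (stop-signal) phase for one agent
#'
#' Go trials draw from the agent's go-RT distribution (misses past the
#' deadline and occasional lapses are logged and carry no RT; direction
#' errors are logged with their RT). Stop trials are resolved by
#' [race_trial()] under the current per-hand SSD, which both start at
#' `ssd_initial_ms` and follow the one-up/one-down staircase.
#'
#' @param agent An `agent_profile`.
#' @param schedule Treatment schedule from [generate_treatment_schedule()].
#' @param config The `study_config`.
#' @param rng_seed Optional seed (defaults to the agent's own).
#' @return The trial log: schedule columns plus `ssd_ms` (NA on go trials),
#'   `outcome` (`go_correct`, `go_error`, `go_miss`, `successful_stop`,
#'   `failed_stop`) and `rt_ms`.
#' @export
simulate_treatment_phase <- function(agent, schedule,
                                     config = cohort_preset(),
                                     rng_seed = agent$rng_seed) {
  stopifnot(inherits(agent, "agent_profile"))
  n <- nrow(schedule)
  deadline <- config$response_deadline_ms
  with_seed_if(rng_seed, {
    go_sample <- rexgauss(n, agent$go_rt[["mu"]], agent$go_rt[["sigma"]],
                          agent$go_rt[["tau"]])
    stop_sample <- rexgauss(n, agent$stop_latency[["mu"]],
                            agent$stop_latency[["sigma"]],
                            agent$stop_latency[["tau"]])
    lapse <- stats::runif(n) < agent$miss_rate
    dir_err <- stats::runif(n) < agent$error_rate

    outcome <- character(n)
    rt <- rep(NA_real_, n)
    ssd_ms <- rep(NA_real_, n)

    go_idx <- which(!schedule$is_stop_trial)
    miss <- lapse[go_idx] | go_sample[go_idx] > deadline
    outcome[go_idx] <- ifelse(miss, "go_miss",
                              ifelse(dir_err[go_idx], "go_error", "go_correct"))
    rt[go_idx[!miss]] <- go_sample[go_idx[!miss]]

    state <- c(left = config$ssd_initial_ms, right = config$ssd_initial_ms)
    for (i in which(schedule$is_stop_trial)) {
      side <- schedule$side[i]
      ssd_ms[i] <- state[[side]]
      go_time <- if (lapse[i] || go_sample[i] > deadline) Inf else go_sample[i]
      if (ssd_ms[i] + stop_sample[i] <= go_time) {
        outcome[i] <- "successful_stop"
      } else {
        outcome[i] <- "failed_stop"
        rt[i] <- go_sample[i]
      }
      state <- staircase_update(state, side, outcome[i],
                                step_ms = config$ssd_step_ms,
                                floor_ms = config$ssd_floor_ms,
                                ceiling_ms = config$ssd_ceiling_ms)
    }
    log <- schedule
    log$ssd_ms <- ssd_ms
    log$outcome <- outcome
    log$rt_ms <- round(rt, 1)
    tibble::as_tibble(log)
  })
}

#' Simulate the auction (valuation) phase for one agent
#'
#' Per trial, subjective worth is
#' `value_sensitivity * internal_value * (1 - devaluation)` plus Gaussian
#' noise whose SD depends on whether the shape's value is explicitly known;
#' the chosen bid is the offered amount closest to worth (ties go to the
#' lower amount).
#'
#' @param agent An `agent_profile` carrying `value_estimates` (i.e. after
#'   [simulate_learning_phase()]).
#' @param schedule Auction schedule from [generate_auction_schedule()].
#' @param config The `study_config` (for the bid sets).
#' @param rng_seed Optional seed (defaults to the agent's own).
#' @return The auction log: schedule columns plus `chosen_amount_cents`.
#' @export
simulate_auction_phase <- function(agent, schedule, config = cohort_preset(),
                                   rng_seed = agent$rng_seed) {
  stopifnot(inherits(agent, "agent_profile"))
  if (is.null(agent$value_estimates)) {
    stop("agent has no value estimates; run simulate_learning_phase() first",
         call. = FALSE)
  }
  with_seed_if(rng_seed, {
    known <- schedule$stimulus_id %in% agent$known_value_shapes
    deval <- ifelse(known, agent$devaluation_effect[["known"]],
                    agent$devaluation_effect[["unknown"]])
    deval[!schedule$stop_paired] <- 0
    internal <- agent$value_estimates[schedule$stimulus_id]
    internal[is.na(internal)] <- 0
    noise_sd <- ifelse(known, agent$bid_noise_sd[["known"]],
                       agent$bid_noise_sd[["unknown"]])
    worth <- agent$value_sensitivity * internal * (1 - deval) +
      stats::rnorm(nrow(schedule), 0, noise_sd)
    chosen <- vapply(seq_len(nrow(schedule)), function(i) {
      set <- config$bid_sets[[schedule$bid_set_id[i]]]
      set[which.min(abs(set - worth[i]))]  # first minimum = lower amount
    }, integer(1))
    log <- schedule
    log$chosen_amount_cents <- chosen
    tibble::as_tibble(log)
  })
}

#' Simulated post-experimental debrief
#'
#' Mirrors the verbal questionnaire: whether the agent reports a feeling of
#' knowing about the reward regularity, which shapes (with their claimed
#' relative value) it can name, and whether it noticed the stop pairing.
#' Named shapes are exactly the agent's `known_value_shapes`, with claimed
#' levels equal to the true ones, so classification ground truth is known
#' by construction.
#'
#' @param agent An `agent_profile`.
#' @param stimuli The agent's stimulus table.
#' @return A list of class `simulated_debrief` with fields
#'   `reported_contingency_feeling`, `named_shapes` (data frame of
#'   `stimulus_id`, `claimed_value_level`), `noticed_stop_pairing`.
#' @export
simulate_debrief <- function(agent, stimuli) {
  stopifnot(inherits(agent, "agent_profile"))
  named <- stimuli[stimuli$stimulus_id %in% agent$known_value_shapes,
                   c("stimulus_id", "value_level")]
  structure(
    list(
      reported_contingency_feeling = agent$knowledge == "explicit",
      named_shapes = data.frame(
        stimulus_id = named$stimulus_id,
        claimed_value_level = as.integer(named$value_level)
      ),
      noticed_stop_pairing = isTRUE(agent$stop_contingency_aware)
    ),
    class = "simulated_debrief"
  )
}
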