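#' Population parameters for simulated cohorts
#'
#' Describes the distribution from which individual [agent_profile()]s are
#' drawn: the explicit/implicit mixture, between-agent variation of the
#' ex-Gaussian go and stop parameters (chosen so group means sit inside
#' the task's monitoring bands: mean go RT near 470 ms within 400-650 ms,
#' mean stop latency near 190 ms within 120-300 ms), lapse and error
#' rates, valuation noise, and the injected devaluation effects that the
#' analysis pipeline is meant to recover.
#'
#' `deval_known` applies to stop-paired shapes whose value an (explicit)
#' agent can name; `deval_unknown` to all other stop-paired shapes, for
#' both groups. Setting both to zero yields a null cohort. Explicit agents
#' know each value level with probability `know_prob_extreme` (levels 1
#' and 4) or `know_prob_mid` (levels 2 and 3), redrawn until at least one
#' level is known; both shapes of a known level are nameable. A small
#' `careless_fraction` of agents bids with `careless_noise_mult`-fold
#' noise, the realistic heavy tail that produces occasional interquartile-
#' range outliers in devaluation scores.
#'
#' @param explicit_fraction Fraction of agents that are explicit learners.
#' @param go_mu,go_sigma,go_tau Mean and (in `*_sd`) between-agent SD of
#'   the go-RT ex-Gaussian parameters (ms).
#' @param go_mu_sd,go_sigma_sd,go_tau_sd See above.
#' @param stop_mu,stop_sigma,stop_tau,stop_mu_sd,stop_sigma_sd,stop_tau_sd
#'   Same for the stop-latency distribution.
#' @param miss_rate,error_rate Mean lapse and direction-error rates.
#' @param value_sensitivity_mean,value_sensitivity_sd Mean and between-agent
#'   SD of the worth slope. The default mean of 0.6 makes subjective worth
#'   sublinear in nominal trained value, so the highest-value shapes
#'   (rewarded-trial mean 400 cents) project inside the offered bid range
#'   (34-324 cents) instead of pinning at the scale ceiling — matching the
#'   under-bidding of top values that the auction's bid sets presuppose.
#' @param bid_noise_known,bid_noise_unknown Bid-noise SD (cents) for
#'   explicitly known vs other shapes.
#' @param deval_known,deval_unknown Injected proportional devaluation of
#'   stop-paired shapes (known vs unknown value).
#' @param know_prob_extreme,know_prob_mid Per-level naming probabilities
#'   for explicit agents.
#' @param stop_aware_fraction Fraction of agents that notice the stop
#'   pairing (debrief bookkeeping).
#' @param careless_fraction,careless_noise_mult Heavy-tail bidding mixture.
#' @return A list of class `population_params`.
#' @export
population_params <- function(explicit_fraction = 22 / 65,
                              go_mu = 400, go_mu_sd = 30,
                              go_sigma = 40, go_sigma_sd = 6,
                              go_tau = 70, go_tau_sd = 12,
                              stop_mu = 150, stop_mu_sd = 12,
                              stop_sigma = 20, stop_sigma_sd = 4,
                              stop_tau = 40, stop_tau_sd = 6,
                              miss_rate = 0.006, error_rate = 0.002,
                              value_sensitivity_mean = 0.6,
                              value_sensitivity_sd = 0.08,
                              bid_noise_known = 25, bid_noise_unknown = 60,
                              deval_known = 0.15, deval_unknown = 0.05,
                              know_prob_extreme = 0.9, know_prob_mid = 0.55,
                              stop_aware_fraction = 8 / 65,
                              careless_fraction = 0.08,
                              careless_noise_mult = 3) {
  stopifnot(explicit_fraction >= 0, explicit_fraction <= 1,
            deval_known >= 0, deval_known < 1,
            deval_unknown >= 0, deval_unknown < 1)
  structure(as.list(environment()), class = "population_params")
}

# Truncated-normal helper for strictly positive agent parameters.
rpos <- function(n, mean, sd, lower = 1e-3) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

# Draw one agent from the population; `stimuli` is its stimulus table.
sample_agent <- function(population, knowledge, stimuli, rng_seed = NULL) {
  with_seed_if(rng_seed, {
    p <- population
    known <- character()
    if (knowledge == "explicit") {
      probs <- c(p$know_prob_extreme, p$know_prob_mid,
                 p$know_prob_mid, p$know_prob_extreme)
      repeat {
        known_levels <- which(stats::runif(4) < probs)
        if (length(known_levels)) break
      }
      known <- stimuli$stimulus_id[stimuli$value_level %in% known_levels]
    }
    careless <- stats::runif(1) < p$careless_fraction
    noise_mult <- if (careless) p$careless_noise_mult else 1
    agent_profile(
      knowledge = knowledge,
      go_rt = c(mu = rpos(1, p$go_mu, p$go_mu_sd, 100),
                sigma = rpos(1, p$go_sigma, p$go_sigma_sd, 5),
                tau = rpos(1, p$go_tau, p$go_tau_sd, 5)),
      stop_latency = c(mu = rpos(1, p$stop_mu, p$stop_mu_sd, 50),
                       sigma = rpos(1, p$stop_sigma, p$stop_sigma_sd, 2),
                       tau = rpos(1, p$stop_tau, p$stop_tau_sd, 2)),
      miss_rate = min(p$miss_rate * exp(stats::rnorm(1, 0, 0.3)), 0.2),
      error_rate = min(p$error_rate * exp(stats::rnorm(1, 0, 0.3)), 0.2),
      known_value_shapes = known,
      value_sensitivity = rpos(1, p$value_sensitivity_mean,
                               p$value_sensitivity_sd, 0.1),
      bid_noise_sd = c(known = p$bid_noise_known * noise_mult,
                       unknown = p$bid_noise_unknown * noise_mult),
      devaluation_effect = c(known = p$deval_known,
                             unknown = p$deval_unknown),
      stop_contingency_aware = stats::runif(1) < p$stop_aware_fraction,
      rng_seed = sample.int(.Machine$integer.max, 1)
    )
  })
}

#' Simulate a full study cohort
#'
#' Runs `n_agents` independently randomized participants through all three
#' phases: per-agent stimulus assignment and schedules, learning (value
#' acquisition), treatment (staircased stop-signal task), auction, and a
#' simulated debrief. The explicit-learner count is
#' `round(explicit_fraction * n_agents)` exactly; which agents are explicit
#' is randomized. All randomness flows from `rng_seed`.
#'
#' @param n_agents Number of participants (>= 1).
#' @param config A `study_config` (default preset `"cohortB"`).
#' @param population A `population_params`.
#' @param rng_seed Integer seed; identical seeds give identical datasets.
#' @return A list of class `devalsim_dataset` with elements `config`,
#'   `stimuli`, `learning`, `treatment`, `auction` (tibbles carrying a
#'   `participant` column), `debriefs` (list keyed by participant), and
#'   `ground_truth` (per-agent true parameters and injected effects).
#' @export
simulate_cohort <- function(n_agents, config = cohort_preset(),
                            population = population_params(),
                            rng_seed = NULL) {
  if (!is.numeric(n_agents) || n_agents < 1) {
    stop("n_agents must be at least 1", call. = FALSE)
  }
  n_agents <- as.integer(n_agents)
  validate_config(config)
  with_seed_if(rng_seed, {
    n_explicit <- as.integer(round(population$explicit_fraction * n_agents))
    knowledge <- rep("implicit", n_agents)
    knowledge[sample.int(n_agents, n_explicit)] <- "explicit"
    agent_seeds <- sample.int(.Machine$integer.max, n_agents)

    stim_l <- learn_l <- treat_l <- auct_l <- gt_l <- vector("list", n_agents)
    debriefs <- stats::setNames(vector("list", n_agents),
                                sprintf("p%03d", seq_len(n_agents)))
    for (a in seq_len(n_agents)) {
      pid <- sprintf("p%03d", a)
      withr::with_seed(agent_seeds[a], {
        stimuli <- assign_stimuli(config)
        agent <- sample_agent(population, knowledge[a], stimuli)
        learning_schedule <- generate_learning_schedule(config, stimuli)
        treatment_schedule <- generate_treatment_schedule(config, stimuli)
        auction_schedule <- generate_auction_schedule(config, stimuli)
        res <- simulate_learning_phase(agent, learning_schedule, config,
                                       rng_seed = NULL)
        agent <- res$agent
        treatment_log <- simulate_treatment_phase(agent, treatment_schedule,
                                                  config, rng_seed = NULL)
        auction_log <- simulate_auction_phase(agent, auction_schedule,
                                              config, rng_seed = NULL)
        debrief <- simulate_debrief(agent, stimuli)
      })
      stim_l[[a]] <- tibble::add_column(stimuli, participant = pid,
                                        .before = 1)
      learn_l[[a]] <- tibble::add_column(res$log, participant = pid,
                                         .before = 1)
      treat_l[[a]] <- tibble::add_column(treatment_log, participant = pid,
                                         .before = 1)
      auct_l[[a]] <- tibble::add_column(auction_log, participant = pid,
                                        .before = 1)
      debriefs[[pid]] <- debrief
      gt_l[[a]] <- tibble::tibble(
        participant = pid,
        knowledge = agent$knowledge,
        true_ssrt_ms = true_ssrt(agent),
        go_rt_mean_ms = unname(agent$go_rt[["mu"]] + agent$go_rt[["tau"]]),
        deval_known = unname(agent$devaluation_effect[["known"]]),
        deval_unknown = unname(agent$devaluation_effect[["unknown"]]),
        n_named_shapes = length(agent$known_value_shapes),
        named_shapes = paste(agent$known_value_shapes, collapse = ";"),
        value_sensitivity = agent$value_sensitivity,
        bid_noise_unknown = unname(agent$bid_noise_sd[["unknown"]]),
        stop_contingency_aware = agent$stop_contingency_aware
      )
    }
    structure(
      list(
        config = config,
        rng_seed = if (!is.null(rng_seed)) as.integer(rng_seed),
        stimuli = dplyr::bind_rows(stim_l),
        learning = dplyr::bind_rows(learn_l),
        treatment = dplyr::bind_rows(treat_l),
        auction = dplyr::bind_rows(auct_l),
        debriefs = debriefs,
        ground_truth = dplyr::bind_rows(gt_l)
      ),
      class = "devalsim_dataset"
    )
  })
}

#' @export
print.devalsim_dataset <- function(x, ...) {
  n <- nrow(x$ground_truth)
  cat(sprintf("<devalsim_dataset> %d participants (%d explicit)\n", n,
              sum(x$ground_truth$knowledge == "explicit")))
  cat(sprintf("  learning %d rows | treatment %d rows | auction %d rows\n",
              nrow(x$learning), nrow(x$treatment), nrow(x$auction)))
  invisible(x)
}
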