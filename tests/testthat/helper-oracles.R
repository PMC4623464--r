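# Independent oracles and shared fixtures for the test suite.

# Brute-force two-sided exact p for the signed-rank test: enumerate all
# 2^n sign assignments of the absolute-value midranks.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Brute-force two-sided exact p for the rank-sum test: enumerate all
# choose(n, nx) labelings.
enumerate_rank_sum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  rx_obs <- sum(r[seq_len(nx)])
  sums <- apply(utils::combn(length(r), nx), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums <= rx_obs), mean(sums >= rx_obs)))
}

# aov() Error-strata fit as the independent general-linear-model check of
# the mixed ANOVA partition; returns named F values.
aov_oracle_f <- function(d, between = TRUE) {
  d$stopping <- factor(d$stopping)
  d$value_level <- factor(d$value_level)
  d$participant <- factor(d$participant)
  form <- if (between) {
    dv ~ knowledge * stopping * value_level +
      Error(participant / (stopping * value_level))
  } else {
    dv ~ stopping * value_level + Error(participant / (stopping * value_level))
  }
  s <- summary(stats::aov(form, data = d))
  f <- unlist(lapply(s, function(st) {
    t <- st[[1]]
    stats::setNames(t[["F value"]], trimws(rownames(t)))
  }))
  f[!is.na(f)]
}

# Random balanced long-format dataset for the 2 x 2 x 4 design.
random_anova_dataset <- function(n_per_group, groups = 2L) {
  n <- n_per_group * groups
  d <- expand.grid(participant = sprintf("s%02d", seq_len(n)),
                   stopping = c("go", "stop"), value_level = 1:4,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- as.integer(sub("s", "", d$participant))
  d$knowledge <- c("explicit", "implicit")[(idx - 1L) %/% n_per_group + 1L]
  d$dv <- stats::rnorm(nrow(d))
  d
}

# One small cohort, simulated once and reused by read-only tests.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(14, cohort_preset("cohortB"),
                                rng_seed = 20240901)
    }
    cache
  }
})

# Treatment-phase-only simulation of one freshly drawn agent; returns the
# log and the agent. Used by recovery/validity tests that do not need the
# other phases.
simulate_treatment_only <- function(config = cohort_preset("cohortB"),
                                    population = population_params(),
                                    knowledge = "implicit") {
  stimuli <- assign_stimuli(config)
  agent <- sample_agent_for_tests(population, knowledge, stimuli)
  schedule <- generate_treatment_schedule(config, stimuli)
  list(agent = agent,
       log = simulate_treatment_phase(agent, schedule, config,
                                      rng_seed = NULL))
}

# population draw without touching unexported internals directly
sample_agent_for_tests <- function(population, knowledge, stimuli) {
  getFromNamespace("sample_agent", "devalsim")(population, knowledge,
                                               stimuli)
}
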