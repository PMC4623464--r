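cfg <- cohort_preset("cohortB")

test_that("race_trial implements the independence race with ties as stops", {
  expect_equal(race_trial(500, 180, 250)$outcome, "successful_stop")
  r <- race_trial(400, 180, 250)
  expect_equal(r$outcome, "failed_stop")
  expect_equal(r$rt_ms, 400)
  expect_equal(race_trial(430, 180, 250)$outcome, "successful_stop")  # tie
  expect_equal(race_trial(550, NA, NA)$outcome, "go_response")
  expect_equal(race_trial(1200, NA, NA)$outcome, "go_miss")
  # unfinished go process cannot lose the race
  expect_equal(race_trial(1200, 600, 500)$outcome, "successful_stop")
})

test_that("staircase moves 50 ms toward failure, clamps, and oscillates", {
  s <- c(left = 250, right = 250)
  s <- staircase_update(s, "left", "successful_stop")
  expect_equal(unname(s), c(300, 250))
  s2 <- staircase_update(c(left = 0, right = 100), "left", "failed_stop",
                         floor_ms = 0)
  expect_equal(s2[["left"]], 0)
  s3 <- c(left = 250, right = 250)
  trace <- numeric(6)
  for (i in 1:6) {
    out <- if (i %% 2 == 1) "successful_stop" else "failed_stop"
    trace[i] <- s3[["left"]]
    s3 <- staircase_update(s3, "left", out)
  }
  expect_equal(trace, c(250, 300, 250, 300, 250, 300))
  expect_error(staircase_update(s3, "left", "go_correct"), "stop-trial")
})

test_that("learning phase repeats failed trials and recovers trained value", {
  st <- assign_stimuli(cfg, rng_seed = 21)
  sched <- generate_learning_schedule(cfg, st, rng_seed = 21)
  clean <- agent_profile(miss_rate = 0, error_rate = 0, rng_seed = 1)
  res <- simulate_learning_phase(clean, sched, cfg)
  expect_equal(nrow(res$log), nrow(sched))
  expect_true(all(res$log$presented_repeats == 1L))
  sloppy <- agent_profile(miss_rate = 0.02, error_rate = 0.08, rng_seed = 2)
  res2 <- simulate_learning_phase(sloppy, sched, cfg)
  expect_equal(nrow(res2$log), nrow(sched))        # completed = scheduled
  expect_gt(sum(res2$log$presented_repeats), nrow(sched))
  expect_true(all(res2$log$correct))

  # internal estimate of a $4 shape: mean of 60 uniform draws on [375, 425],
  # standard error 50/sqrt(12)/sqrt(60) ~ 1.9 cents
  top <- st$stimulus_id[st$value_level == 4]
  ests <- res$agent$value_estimates[top]
  expect_true(all(abs(ests - 400) < 4.5 * 50 / sqrt(12) / sqrt(60) + 0.5))
})

test_that("failed-stop RTs are faster than go RTs for a race agent", {
  set.seed(88)
  sim <- simulate_treatment_only()
  m <- compute_stop_metrics(sim$log)
  expect_gte(m$n_stop, 100)
  expect_lt(m$failed_stop_rt_ms, m$go_rt_ms)
  expect_true(m$race_valid)
})

test_that("an unstoppable agent yields p(stop) near zero with SSD at floor", {
  set.seed(3)
  st <- assign_stimuli(cfg)
  slow_stop <- agent_profile(
    stop_latency = c(mu = 2000, sigma = 20, tau = 40),
    miss_rate = 0, error_rate = 0
  )
  sched <- generate_treatment_schedule(cfg, st)
  log <- simulate_treatment_phase(slow_stop, sched, cfg, rng_seed = NULL)
  m <- compute_stop_metrics(log)
  expect_lt(m$p_stop, 0.02)
  # staircase driven to the floor
  late <- log[log$is_stop_trial & log$trial_index > 200, ]
  expect_lt(mean(late$ssd_ms), 60)
})

test_that("without stop trials the staircase never moves", {
  cfg0 <- study_config(stop_fraction_on_stop_shapes = 0)
  st <- assign_stimuli(cfg0, rng_seed = 12)
  sched <- generate_treatment_schedule(cfg0, st, rng_seed = 12)
  agent <- agent_profile(rng_seed = 9)
  log <- simulate_treatment_phase(agent, sched, cfg0)
  expect_true(all(is.na(log$ssd_ms)))
  expect_false(any(log$outcome %in% c("successful_stop", "failed_stop")))
})

test_that("auction choices are the nearest offered amount, lower on ties", {
  st <- assign_stimuli(cfg, rng_seed = 30)
  sched <- generate_auction_schedule(cfg, st, rng_seed = 30)
  agent <- agent_profile(
    bid_noise_sd = c(known = 0, unknown = 0),
    devaluation_effect = c(known = 0, unknown = 0),
    rng_seed = 5
  )
  agent$value_estimates <- stats::setNames(rep(410, 8), st$stimulus_id)
  log <- simulate_auction_phase(agent, sched, cfg)
  set5 <- log[log$bid_set_id == 5, ]
  expect_true(all(set5$chosen_amount_cents == 324L))  # 410 -> top of 54..324
  # equal-value stop and go shapes receive identical bids without effect
  lev <- auction_bid_levels(log, cfg)
  means <- tapply(lev$bid_level, lev$stop_paired, mean)
  expect_equal(unname(diff(means)), 0)
  # midpoint ties resolve to the lower amount: worth 51 in set (34, 68, ...)
  agent2 <- agent
  agent2$value_estimates <- stats::setNames(rep(51, 8), st$stimulus_id)
  log2 <- simulate_auction_phase(agent2, sched, cfg)
  expect_true(all(log2$chosen_amount_cents[log2$bid_set_id == 1] == 34L))
})

test_that("devaluation shows up in bids and scales with the injected effect", {
  st <- assign_stimuli(cfg, rng_seed = 31)
  sched <- generate_auction_schedule(cfg, st, rng_seed = 31)
  mk <- function(effect) {
    a <- agent_profile(
      bid_noise_sd = c(known = 0, unknown = 0),
      devaluation_effect = c(known = effect, unknown = effect),
      rng_seed = 6
    )
    a$value_estimates <- stats::setNames(
      st$mean_value_cents + 0, st$stimulus_id)
    a
  }
  gaps <- vapply(c(0, 0.1, 0.2), function(eff) {
    log <- auction_bid_levels(simulate_auction_phase(mk(eff), sched, cfg), cfg)
    means <- tapply(log$bid_level, log$stop_paired, mean)
    means[["FALSE"]] - means[["TRUE"]]
  }, numeric(1))
  expect_equal(gaps[1], 0)
  expect_true(all(diff(gaps) > 0))
})

test_that("simulated debriefs carry ground truth consistent with knowledge", {
  ds <- shared_cohort()
  gt <- ds$ground_truth
  for (pid in gt$participant) {
    d <- ds$debriefs[[pid]]
    if (gt$knowledge[gt$participant == pid] == "explicit") {
      expect_true(d$reported_contingency_feeling)
      expect_gt(nrow(d$named_shapes), 0)
    } else {
      expect_false(d$reported_contingency_feeling)
      expect_equal(nrow(d$named_shapes), 0)
    }
  }
})
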