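cfg_a <- cohort_preset("cohortA")
cfg_b <- cohort_preset("cohortB")

test_that("learning schedules honor counts, reward grid and blocks", {
  for (cfg in list(cfg_a, cfg_b)) {
    st <- assign_stimuli(cfg, rng_seed = 5)
    sched <- generate_learning_schedule(cfg, st, rng_seed = 5)
    expect_equal(nrow(sched), 8L * cfg$learning_trials_per_shape)
    per <- split(sched, sched$stimulus_id)
    for (d in per) {
      expect_equal(nrow(d), cfg$learning_trials_per_shape)
      expect_equal(sum(d$scheduled_reward_cents == 0),
                   cfg$learning_zero_reward_trials_per_shape)
      mu <- st$mean_value_cents[st$stimulus_id == d$stimulus_id[1]]
      nz <- d$scheduled_reward_cents[d$scheduled_reward_cents > 0]
      expect_true(all(nz >= mu - cfg$reward_dispersion_cents &
                        nz <= mu + cfg$reward_dispersion_cents))
      # stratified quadrants when divisible by 4
      if (cfg$learning_trials_per_shape %% 4L == 0L) {
        expect_equal(as.vector(table(d$quadrant)),
                     rep(cfg$learning_trials_per_shape / 4L, 4))
      }
    }
    expect_equal(as.vector(table(sched$block)),
                 rep(nrow(sched) / cfg$learning_blocks, cfg$learning_blocks))
    expect_equal(sched$trial_index, seq_len(nrow(sched)) - 1L)
  }
})

test_that("a $4 shape's rewards lie within 375-425 cents", {
  st <- assign_stimuli(cfg_b, rng_seed = 11)
  sched <- generate_learning_schedule(cfg_b, st, rng_seed = 11)
  top <- st$stimulus_id[st$value_level == 4]
  r <- sched$scheduled_reward_cents[sched$stimulus_id %in% top]
  r <- r[r > 0]
  expect_true(all(r >= 375 & r <= 425))
})

test_that("degenerate and indivisible learning configs are handled", {
  st <- assign_stimuli(cfg_b, rng_seed = 1)
  cfg0 <- study_config(learning_trials_per_shape = 0,
                       learning_zero_reward_trials_per_shape = 0)
  expect_equal(nrow(generate_learning_schedule(cfg0, st)), 0L)
  cfg_bad <- study_config(learning_trials_per_shape = 50,
                          learning_zero_reward_trials_per_shape = 10,
                          learning_blocks = 7)
  expect_error(generate_learning_schedule(cfg_bad, st), "not divisible")
})

test_that("treatment schedules give stop signals only to stop shapes, at the design rate", {
  for (cfg in list(cfg_a, cfg_b)) {
    st <- assign_stimuli(cfg, rng_seed = 3)
    sched <- generate_treatment_schedule(cfg, st, rng_seed = 3)
    expect_equal(nrow(sched), 8L * cfg$treatment_trials_per_shape)
    n_stop_per <- round(0.75 * cfg$treatment_trials_per_shape)
    for (sid in st$stimulus_id) {
      d <- sched[sched$stimulus_id == sid, ]
      paired <- st$stop_paired[st$stimulus_id == sid]
      expect_equal(sum(d$is_stop_trial), if (paired) n_stop_per else 0L)
      expect_equal(as.vector(table(d$side)),
                   rep(cfg$treatment_trials_per_shape / 2L, 2))
    }
    expect_equal(mean(sched$is_stop_trial), 0.375)
  }
})

test_that("zero stop fraction and non-integral stop counts behave per contract", {
  st <- assign_stimuli(cfg_b, rng_seed = 2)
  cfg0 <- study_config(stop_fraction_on_stop_shapes = 0)
  expect_false(any(generate_treatment_schedule(cfg0, st)$is_stop_trial))
  cfg_bad <- study_config(treatment_trials_per_shape = 42,
                          treatment_blocks = 8,
                          stop_fraction_on_stop_shapes = 0.75)
  expect_error(generate_treatment_schedule(cfg_bad, st), "not an integer")
})

test_that("auction schedules present each shape-set pair exactly twice", {
  st <- assign_stimuli(cfg_b, rng_seed = 4)
  sched <- generate_auction_schedule(cfg_b, st, rng_seed = 4)
  expect_equal(nrow(sched), 80L)
  pair_counts <- table(sched$stimulus_id, sched$bid_set_id)
  expect_true(all(pair_counts == 2L))
  expect_equal(as.vector(table(sched$block)), rep(20L, 4))
  # per-trial button permutation covers the set
  for (i in c(1, 40, 80)) {
    amounts <- sort(as.integer(strsplit(sched$button_mapping[i], ",")[[1]]))
    expect_equal(amounts, cfg_b$bid_sets[[sched$bid_set_id[i]]])
  }
})

test_that("schedule generation is byte-identical per seed through CSV", {
  st <- assign_stimuli(cfg_b, rng_seed = 9)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(generate_treatment_schedule(cfg_b, st, rng_seed = 77), p1)
  write_trials(generate_treatment_schedule(cfg_b, st, rng_seed = 77), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_trials(p1)
  fwd <- generate_treatment_schedule(cfg_b, st, rng_seed = 77)
  expect_equal(as.data.frame(back), as.data.frame(fwd))
})

test_that("counting invariants hold over randomized valid configs", {
  set.seed(31)
  for (i in 1:5) {
    n_per <- sample(c(8L, 12L, 20L), 1)
    cfg <- study_config(
      learning_trials_per_shape = n_per,
      learning_zero_reward_trials_per_shape = sample.int(n_per %/% 4L, 1),
      learning_blocks = sample(c(1L, 2L, 4L), 1),
      treatment_trials_per_shape = 8L,
      treatment_blocks = sample(c(2L, 4L), 1),
      stop_fraction_on_stop_shapes = 0.75
    )
    st <- assign_stimuli(cfg, rng_seed = i)
    learn <- generate_learning_schedule(cfg, st, rng_seed = i)
    expect_equal(as.vector(table(learn$stimulus_id)), rep(n_per, 8))
    expect_equal(sum(learn$scheduled_reward_cents == 0),
                 8L * cfg$learning_zero_reward_trials_per_shape)
    treat <- generate_treatment_schedule(cfg, st, rng_seed = i)
    expect_equal(sum(treat$is_stop_trial), 4L * 6L)
  }
})
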