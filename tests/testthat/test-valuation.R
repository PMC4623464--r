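cfg <- cohort_preset("cohortB")

test_that("bid levels are the rank of the chosen amount within its set", {
  expect_equal(bid_to_level(204, c(34, 68, 102, 136, 170, 204)), 6L)
  expect_equal(bid_to_level(54, c(54, 108, 162, 216, 270, 324)), 1L)
  expect_equal(bid_to_level(c(117, 39), list(cfg$bid_sets[[2]],
                                             cfg$bid_sets[[2]])),
               c(3L, 1L))
  expect_error(bid_to_level(100, cfg$bid_sets[[1]]), "not in the bid set")
})

test_that("levels ignore the on-screen button permutation", {
  st <- assign_stimuli(cfg, rng_seed = 77)
  sched <- generate_auction_schedule(cfg, st, rng_seed = 77)
  agent <- agent_profile(rng_seed = 8)
  agent$value_estimates <- stats::setNames(rep(150, 8), st$stimulus_id)
  log <- simulate_auction_phase(agent, sched, cfg)
  lv1 <- auction_bid_levels(log, cfg)$bid_level
  log$button_mapping <- vapply(log$bid_set_id, function(s)
    paste(rev(cfg$bid_sets[[s]]), collapse = ","), character(1))
  expect_equal(auction_bid_levels(log, cfg)$bid_level, lv1)
})

test_that("knowledge classification requires a feeling plus one accurate name", {
  st <- assign_stimuli(cfg, rng_seed = 50)
  high <- st[st$value_level == 4, ][1, ]
  mk_debrief <- function(feeling, ids, claims) {
    list(reported_contingency_feeling = feeling,
         named_shapes = data.frame(stimulus_id = ids,
                                   claimed_value_level = claims),
         noticed_stop_pairing = FALSE)
  }
  expect_equal(classify_knowledge(
    mk_debrief(TRUE, high$stimulus_id, 4L), st), "explicit")
  expect_equal(classify_knowledge(
    mk_debrief(FALSE, character(), integer()), st), "implicit")
  # naming a shape with the wrong relative value does not count
  expect_equal(classify_knowledge(
    mk_debrief(TRUE, high$stimulus_id, 1L), st), "implicit")
  # feeling without any name does not count
  expect_equal(classify_knowledge(
    mk_debrief(TRUE, character(), integer()), st), "implicit")
})

test_that("devaluation scores are go minus stop mean levels", {
  ds <- shared_cohort()
  cells <- bid_cell_summaries(ds$auction, ds$config)
  scores <- devaluation_scores(ds$auction, ds$config)
  pid <- scores$participant[1]
  d <- cells[cells$participant == pid, ]
  expect_equal(scores$devaluation_score[1],
               mean(d$mean_bid_level[d$stopping == "go"]) -
                 mean(d$mean_bid_level[d$stopping == "stop"]))
  expect_true(all(abs(scores$devaluation_score) <= 5))
  # constructed: go levels all 4, stop levels all 3 -> score 1
  fake <- ds$auction[ds$auction$participant == pid, ]
  go4 <- vapply(seq_len(nrow(fake)), function(i)
    cfg$bid_sets[[fake$bid_set_id[i]]][if (fake$stop_paired[i]) 3L else 4L],
    integer(1))
  fake$chosen_amount_cents <- go4
  expect_equal(devaluation_scores(fake, cfg)$devaluation_score, 1.0)
})

test_that("shuffling stop labels symmetrizes devaluation scores around zero", {
  ds <- shared_cohort()
  pid <- "p003"
  log <- ds$auction[ds$auction$participant == pid, ]
  set.seed(15)
  scores <- replicate(60, {
    st <- ds$stimuli[ds$stimuli$participant == pid, ]
    new_stop <- unlist(lapply(split(st$stimulus_id, st$value_level),
                              sample, size = 1))
    log$stop_paired <- log$stimulus_id %in% new_stop
    devaluation_scores(log, ds$config)$devaluation_score
  })
  expect_lt(abs(mean(scores)), max(abs(scores)))
  expect_gt(sum(scores > 0), 5)
  expect_gt(sum(scores < 0), 5)
})

test_that("IQR filter removes gross outliers but spares homogeneous groups", {
  # all-equal values: bounds collapse onto the value, nothing removed
  res <- iqr_outlier_filter(rep(0.3, 10))
  expect_equal(res$removed, integer())
  # a gross outlier in one group is removed; the other group untouched
  x <- c(rnorm(20, 0, 0.1), 50)
  g <- rep(c("a", "b"), c(10, 11))
  res2 <- iqr_outlier_filter(x, g)
  expect_true(21 %in% res2$removed)
  expect_false(any(res2$removed <= 10))
  # standard-normal samples of 43 rarely lose more than a few points
  set.seed(9)
  removed <- vapply(1:50, function(i)
    length(iqr_outlier_filter(rnorm(43))$removed), numeric(1))
  expect_lt(mean(removed), 2.5)
  # groups too small pass through with a warning
  expect_warning(iqr_outlier_filter(c(1, 2, 100), rep("tiny", 3)),
                 "fewer than")
})
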