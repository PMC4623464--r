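cfg <- cohort_preset("cohortB")

# deterministic two-participant treatment log built by hand
toy_log <- function(go_rts, ssds, outcomes, sides = NULL) {
  n_go <- length(go_rts)
  n_stop <- length(ssds)
  if (is.null(sides)) sides <- rep(c("left", "right"), length.out = n_stop)
  tibble::tibble(
    trial_index = seq_len(n_go + n_stop) - 1L,
    block = 1L,
    stimulus_id = "white_square",
    value_level = 1L,
    stop_paired = TRUE,
    side = c(rep("left", n_go), sides),
    is_stop_trial = rep(c(FALSE, TRUE), c(n_go, n_stop)),
    ssd_ms = c(rep(NA_real_, n_go), ssds),
    outcome = c(rep("go_correct", n_go), outcomes),
    rt_ms = c(go_rts, ifelse(outcomes == "failed_stop", 380, NA_real_))
  )
}

test_that("mean-method SSRT is go RT minus mean SSD", {
  log <- toy_log(go_rts = c(460, 470, 471), ssds = c(270, 280, 287),
                 outcomes = c("successful_stop", "failed_stop",
                              "successful_stop"))
  m <- compute_stop_metrics(log)
  expect_equal(m$go_rt_ms, 467)
  expect_equal(m$mean_ssd_ms, 279)
  expect_equal(m$ssrt_ms, 188)
  expect_equal(m$p_stop, 2 / 3)
  expect_true(m$race_valid)  # 380 < 467
})

test_that("p(stop) is successes over stop trials", {
  log <- toy_log(rep(500, 4), ssds = rep(250, 132),
                 outcomes = rep(c("successful_stop", "failed_stop"), 66))
  expect_equal(compute_stop_metrics(log)$p_stop, 0.5)
})

test_that("go RT excludes misses and direction errors", {
  log <- toy_log(c(400, 600), c(250), c("successful_stop"))
  log$outcome[1] <- "go_error"
  m <- compute_stop_metrics(log)
  expect_equal(m$go_rt_ms, 600)
  expect_equal(m$error_rate, 0.5)
  log2 <- toy_log(c(400), numeric(), character())
  expect_error(compute_stop_metrics(log2), "at least one")
})

test_that("mean-method identity holds on every simulated log", {
  ds <- shared_cohort()
  metrics <- stop_metrics_by_participant(ds$treatment)
  expect_equal(metrics$ssrt_ms, metrics$go_rt_ms - metrics$mean_ssd_ms)
})

test_that("SSRT is invariant to relabeling the hands", {
  ds <- shared_cohort()
  one <- ds$treatment[ds$treatment$participant == "p001", ]
  flipped <- one
  flipped$side <- ifelse(one$side == "left", "right", "left")
  expect_equal(compute_stop_metrics(flipped)$ssrt_ms,
               compute_stop_metrics(one)$ssrt_ms)
})

test_that("race validity test uses n - 1 degrees of freedom and flags constants", {
  ds <- shared_cohort()
  res <- check_race_validity(ds$treatment)
  n <- length(unique(ds$treatment$participant))
  expect_equal(res$test$df, n - 1)
  expect_true(all(res$per_participant$race_valid, na.rm = TRUE))
  expect_equal(res$test$effect_size_type, "cohen_d")
  # equal mean RTs on both trial types violate the race prediction
  log <- toy_log(c(400, 400), c(250, 260), c("failed_stop", "failed_stop"))
  log$rt_ms[log$outcome == "failed_stop"] <- 400
  expect_false(compute_stop_metrics(log)$race_valid)
})

test_that("exclusion bounds remove and annotate the right participants", {
  base <- stop_metrics_by_participant(shared_cohort()$treatment)
  good <- base[1, ]
  good$p_stop <- 0.52; good$ssrt_ms <- 188; good$race_valid <- TRUE
  bad1 <- good; bad1$participant <- "px1"; bad1$p_stop <- 0.95
  bad2 <- good; bad2$participant <- "px2"; bad2$ssrt_ms <- 350
  bad3 <- good; bad3$participant <- "px3"; bad3$race_valid <- FALSE
  metrics <- dplyr::bind_rows(good, bad1, bad2, bad3)
  res <- apply_exclusions(metrics)
  expect_equal(res$retained$participant, good$participant)
  expect_equal(res$excluded$reason, c("p_stop", "ssrt", "race_model"))
  # a cohort of 4 with 3 out-of-bounds leaves 1
  expect_equal(nrow(res$retained) + nrow(res$excluded), 4L)
})

test_that("shifting the stop-latency distribution shifts estimated SSRT linearly", {
  set.seed(404)
  delta <- 50
  est <- function(pop) {
    mean(replicate(200, {
      sim <- simulate_treatment_only(population = pop)
      compute_stop_metrics(sim$log)$ssrt_ms - true_ssrt(sim$agent)
    }))
  }
  bias0 <- est(population_params())
  biasd <- est(population_params(stop_mu = 150 + delta))
  # the +delta cohort's estimate tracks its (shifted) true SSRT, so the
  # bias difference stays within 10 ms
  expect_lt(abs(biasd - bias0), 10)
})

test_that("block monitoring reports out-of-band behavior", {
  ds <- shared_cohort()
  one <- ds$treatment[ds$treatment$participant == "p002", ]
  rep <- monitor_blocks(one)
  expect_equal(nrow(rep), max(one$block))
  slow <- one
  slow$rt_ms[slow$outcome == "go_correct"] <- 900
  rep2 <- monitor_blocks(slow)
  expect_true(all(grepl("go_rt", rep2$warnings)))
})
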