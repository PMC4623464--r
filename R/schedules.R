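#' Generate the learning-phase trial schedule
#'
#' Each shape receives `learning_trials_per_shape` trials, of which exactly
#' `learning_zero_reward_trials_per_shape` pay zero; the remaining rewards
#' are drawn uniformly on the integer cent grid
#' `[mean - dispersion, mean + dispersion]` for that shape's value level.
#' Quadrants are stratified (balanced) per shape when the trial count
#' divides by four and sampled i.i.d. uniform otherwise. All trials are
#' globally shuffled once and then split into `learning_blocks` contiguous
#' equal blocks.
#'
#' @param config A `study_config`.
#' @param stimuli Stimulus table from [assign_stimuli()].
#' @param rng_seed Optional integer seed; schedules are pure functions of
#'   `(config, stimuli, seed)`.
#'
#' @return A tibble with columns `trial_index` (0-based), `block` (1-based),
#'   `stimulus_id`, `value_level`, `stop_paired`, `quadrant` (1-4), and
#'   `scheduled_reward_cents` (0 on scheduled-zero trials).
#' @export
generate_learning_schedule <- function(config, stimuli, rng_seed = NULL) {
  validate_config(config)
  validate_stimuli(stimuli)
  n_per <- config$learning_trials_per_shape
  n_zero <- config$learning_zero_reward_trials_per_shape
  total <- 8L * n_per
  if (total == 0L) return(empty_learning_schedule())
  if (total %% config$learning_blocks != 0L) {
    stop("learning trials (", total, ") not divisible by ",
         config$learning_blocks, " blocks", call. = FALSE)
  }
  disp <- config$reward_dispersion_cents
  with_seed_if(rng_seed, {
    rows <- lapply(seq_len(8L), function(i) {
      mean_cents <- stimuli$mean_value_cents[i]
      reward <- c(
        rep(0L, n_zero),
        sample(seq.int(mean_cents - disp, mean_cents + disp),
               n_per - n_zero, replace = TRUE)
      )
      quadrant <- if (n_per %% 4L == 0L) {
        sample(rep(1:4, n_per %/% 4L))
      } else {
        sample(1:4, n_per, replace = TRUE)
      }
      data.frame(
        stimulus_id = stimuli$stimulus_id[i],
        value_level = stimuli$value_level[i],
        stop_paired = stimuli$stop_paired[i],
        quadrant = as.integer(quadrant),
        scheduled_reward_cents = as.integer(sample(reward))
      )
    })
    sched <- do.call(rbind, rows)
    sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
    finalize_schedule(sched, config$learning_blocks)
  })
}

#' Generate the treatment-phase (stop-signal) trial schedule
#'
#' Each shape receives `treatment_trials_per_shape` trials. Stop-paired
#' shapes carry a stop signal on exactly
#' `stop_fraction_on_stop_shapes * treatment_trials_per_shape` of their
#' trials (the product must be integral); never-stopped shapes carry none.
#' Left/right presentation sides are balanced per shape (the odd trial, if
#' any, is assigned at random). Trials are globally shuffled and split into
#' `treatment_blocks` contiguous equal blocks.
#'
#' @inheritParams generate_learning_schedule
#' @return A tibble with columns `trial_index`, `block`, `stimulus_id`,
#'   `value_level`, `stop_paired`, `side` (`"left"`/`"right"`), and
#'   `is_stop_trial`.
#' @export
generate_treatment_schedule <- function(config, stimuli, rng_seed = NULL) {
  validate_config(config)
  validate_stimuli(stimuli)
  n_per <- config$treatment_trials_per_shape
  total <- 8L * n_per
  if (total == 0L) return(empty_treatment_schedule())
  if (total %% config$treatment_blocks != 0L) {
    stop("treatment trials (", total, ") not divisible by ",
         config$treatment_blocks, " blocks", call. = FALSE)
  }
  n_stop_raw <- config$stop_fraction_on_stop_shapes * n_per
  if (abs(n_stop_raw - round(n_stop_raw)) > 1e-8) {
    stop("stop fraction x trials per shape (", n_stop_raw,
         ") is not an integer", call. = FALSE)
  }
  n_stop <- as.integer(round(n_stop_raw))
  with_seed_if(rng_seed, {
    rows <- lapply(seq_len(8L), function(i) {
      sides <- sample(rep(c("left", "right"), length.out = n_per))
      if (n_per %% 2L == 1L) sides[n_per] <- sample(c("left", "right"), 1L)
      is_stop <- if (stimuli$stop_paired[i]) {
        sample(rep(c(TRUE, FALSE), c(n_stop, n_per - n_stop)))
      } else {
        rep(FALSE, n_per)
      }
      data.frame(
        stimulus_id = stimuli$stimulus_id[i],
        value_level = stimuli$value_level[i],
        stop_paired = stimuli$stop_paired[i],
        side = sides,
        is_stop_trial = is_stop
      )
    })
    sched <- do.call(rbind, rows)
    sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
    finalize_schedule(sched, config$treatment_blocks)
  })
}

#' Generate the auction-phase trial schedule
#'
#' Every (shape, bid set) pair occurs exactly twice, giving
#' `8 x 2 x n_sets` trials (80 for the default five sets), in globally
#' shuffled order, split into `auction_blocks` contiguous equal blocks.
#' Each trial carries an independent random permutation of the six amounts
#' over the six response keys.
#'
#' @inheritParams generate_learning_schedule
#' @return A tibble with columns `trial_index`, `block`, `stimulus_id`,
#'   `value_level`, `stop_paired`, `bid_set_id` (1-based), and
#'   `button_mapping` (the six amounts in key order, comma-separated).
#' @export
generate_auction_schedule <- function(config, stimuli, rng_seed = NULL) {
  validate_config(config)
  validate_stimuli(stimuli)
  n_sets <- length(config$bid_sets)
  if (config$auction_presentations_per_shape != 2L * n_sets) {
    stop("auction presentations per shape must equal 2 x number of bid sets",
         call. = FALSE)
  }
  total <- 8L * config$auction_presentations_per_shape
  if (total %% config$auction_blocks != 0L) {
    stop("auction trials (", total, ") not divisible by ",
         config$auction_blocks, " blocks", call. = FALSE)
  }
  with_seed_if(rng_seed, {
    sched <- expand.grid(
      rep_id = 1:2, bid_set_id = seq_len(n_sets), row = seq_len(8L),
      KEEP.OUT.ATTRS = FALSE
    )
    sched <- data.frame(
      stimulus_id = stimuli$stimulus_id[sched$row],
      value_level = stimuli$value_level[sched$row],
      stop_paired = stimuli$stop_paired[sched$row],
      bid_set_id = as.integer(sched$bid_set_id)
    )
    sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
    sched$button_mapping <- vapply(
      sched$bid_set_id,
      function(s) paste(sample(config$bid_sets[[s]]), collapse = ","),
      character(1)
    )
    finalize_schedule(sched, config$auction_blocks)
  })
}

# Shared tail: assign 0-based trial indices and contiguous equal blocks.
finalize_schedule <- function(sched, n_blocks) {
  n <- nrow(sched)
  sched$trial_index <- seq_len(n) - 1L
  sched$block <- as.integer(rep(seq_len(n_blocks), each = n %/% n_blocks))
  rownames(sched) <- NULL
  tibble::as_tibble(sched[, c("trial_index", "block",
                              setdiff(names(sched), c("trial_index", "block")))])
}

empty_learning_schedule <- function() {
  tibble::tibble(trial_index = integer(), block = integer(),
                 stimulus_id = character(), value_level = integer(),
                 stop_paired = logical(), quadrant = integer(),
                 scheduled_reward_cents = integer())
}

empty_treatment_schedule <- function() {
  tibble::tibble(trial_index = integer(), block = integer(),
                 stimulus_id = character(), value_level = integer(),
                 stop_paired = logical(), side = character(),
                 is_stop_trial = logical())
}

#' Write / read a trial schedule or log as CSV
#'
#' One row per trial, mandatory header, UTF-8, `"."` decimal separator,
#' 0-based `trial_index`. Re-running a generator with the same seed and
#' writing again produces byte-identical files.
#'
#' @param x A schedule or trial-log tibble.
#' @param path Output CSV path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   tibble.
#' @export
write_trials <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in intersect(c("stop_paired", "is_stop_trial", "correct",
                          "stop_contingency_aware"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  tibble::as_tibble(df)
}
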