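#' Build a study configuration
#'
#' A `study_config` captures every design parameter of the three-phase
#' paradigm: the implicit value-learning phase (reward schedule), the
#' stop-signal treatment phase (stop pairing and SSD staircase), and the
#' auction valuation phase (bid sets and presentation counts).
#'
#' Monetary quantities are integer cents; durations are milliseconds.
#' The four reward-schedule means (50, 100, 200, 400 cents by default) are
#' the means of the *rewarded* trials; because a fixed subset of trials pays
#' zero, the per-trial expected values are lower (40, 80, 160, 320 cents for
#' the default schedule), and the default bid sets span exactly that range.
#'
#' @param learning_trials_per_shape Completed learning trials per shape.
#' @param learning_zero_reward_trials_per_shape How many of those pay zero.
#' @param learning_blocks Number of equal contiguous learning blocks.
#' @param treatment_trials_per_shape Treatment trials per shape.
#' @param treatment_blocks Number of equal treatment blocks.
#' @param stop_fraction_on_stop_shapes Fraction of a stop-paired shape's
#'   trials that carry a stop signal (0.75 by default, i.e. 27 of 36).
#' @param auction_presentations_per_shape Auction trials per shape; must be
#'   twice the number of bid sets.
#' @param auction_blocks Number of equal auction blocks.
#' @param value_means_cents Strictly increasing vector of the four
#'   rewarded-trial means (cents).
#' @param reward_dispersion_cents Half-width of the uniform reward
#'   dispersion around each mean (cents).
#' @param ssd_initial_ms,ssd_step_ms,ssd_floor_ms,ssd_ceiling_ms Staircase
#'   parameters for the stop-signal delay (per-hand, +step after a
#'   successful stop, -step after a failed stop, clamped to
#'   `[floor, ceiling]`).
#' @param bid_sets List of strictly increasing 6-vectors of cent amounts.
#' @param response_deadline_ms Response deadline for go responses.
#' @param rng_seed Optional integer seed recorded with the config.
#'
#' @return A list of class `study_config`.
#' @seealso [cohort_preset()] for the two shipped configurations.
#' @export
study_config <- function(learning_trials_per_shape = 72,
                         learning_zero_reward_trials_per_shape = 12,
                         learning_blocks = 6,
                         treatment_trials_per_shape = 44,
                         treatment_blocks = 11,
                         stop_fraction_on_stop_shapes = 0.75,
                         auction_presentations_per_shape = 10,
                         auction_blocks = 4,
                         value_means_cents = c(50L, 100L, 200L, 400L),
                         reward_dispersion_cents = 25L,
                         ssd_initial_ms = 250,
                         ssd_step_ms = 50,
                         ssd_floor_ms = 0,
                         ssd_ceiling_ms = 1000,
                         bid_sets = default_bid_sets(),
                         response_deadline_ms = 1000,
                         rng_seed = NULL) {
  config <- list(
    learning_trials_per_shape = as.integer(learning_trials_per_shape),
    learning_zero_reward_trials_per_shape =
      as.integer(learning_zero_reward_trials_per_shape),
    learning_blocks = as.integer(learning_blocks),
    treatment_trials_per_shape = as.integer(treatment_trials_per_shape),
    treatment_blocks = as.integer(treatment_blocks),
    stop_fraction_on_stop_shapes = stop_fraction_on_stop_shapes,
    auction_presentations_per_shape = as.integer(auction_presentations_per_shape),
    auction_blocks = as.integer(auction_blocks),
    value_means_cents = as.integer(value_means_cents),
    reward_dispersion_cents = as.integer(reward_dispersion_cents),
    ssd_initial_ms = ssd_initial_ms,
    ssd_step_ms = ssd_step_ms,
    ssd_floor_ms = ssd_floor_ms,
    ssd_ceiling_ms = ssd_ceiling_ms,
    bid_sets = lapply(bid_sets, as.integer),
    response_deadline_ms = response_deadline_ms,
    rng_seed = if (!is.null(rng_seed)) as.integer(rng_seed)
  )
  class(config) <- "study_config"
  validate_config(config)
  config
}

#' The five default auction bid sets (cents)
#'
#' Five strictly increasing sets of six amounts; their union spans 34-324
#' cents, covering the per-trial expected values of the default reward
#' schedule (40-320 cents).
#'
#' @return A list of five integer 6-vectors.
#' @export
default_bid_sets <- function() {
  list(
    c(34L, 68L, 102L, 136L, 170L, 204L),
    c(39L, 78L, 117L, 156L, 195L, 234L),
    c(44L, 88L, 132L, 176L, 220L, 264L),
    c(49L, 98L, 147L, 196L, 245L, 294L),
    c(54L, 108L, 162L, 216L, 270L, 324L)
  )
}

#' Preset study configurations
#'
#' Two cohorts are shipped. `"cohortA"`: 50 learning trials per shape
#' (40 rewarded, 10 zero) in 4 blocks and 36 treatment trials per shape in
#' 8 blocks. `"cohortB"`: 72 learning trials per shape (60 rewarded,
#' 12 zero) in 6 blocks and 44 treatment trials per shape in 11 blocks.
#' All other parameters are shared.
#'
#' @param name `"cohortA"` or `"cohortB"`.
#' @return A `study_config`.
#' @export
cohort_preset <- function(name = c("cohortB", "cohortA")) {
  name <- match.arg(name)
  if (name == "cohortA") {
    study_config(
      learning_trials_per_shape = 50,
      learning_zero_reward_trials_per_shape = 10,
      learning_blocks = 4,
      treatment_trials_per_shape = 36,
      treatment_blocks = 8
    )
  } else {
    study_config()
  }
}

#' Validate a study configuration
#'
#' Checks the structural invariants: four strictly increasing value means,
#' five strictly increasing 6-entry bid sets, stop fraction in `[0, 1]`,
#' zero-reward count not exceeding the per-shape trial count, positive
#' staircase step, floor below ceiling, and presentations equal to twice
#' the number of bid sets.
#'
#' @param config A `study_config`.
#' @return `config`, invisibly; errors with an informative message otherwise.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "study_config"))
  fail <- function(msg) stop("invalid study_config: ", msg, call. = FALSE)
  v <- config$value_means_cents
  if (length(v) != 4L || any(diff(v) <= 0)) {
    fail("value_means_cents must be 4 strictly increasing amounts")
  }
  if (length(config$bid_sets) < 1L) fail("at least one bid set required")
  for (set in config$bid_sets) {
    if (length(set) != 6L || any(diff(set) <= 0)) {
      fail("each bid set must contain 6 strictly increasing amounts")
    }
  }
  f <- config$stop_fraction_on_stop_shapes
  if (!is.numeric(f) || f < 0 || f > 1) fail("stop fraction must lie in [0, 1]")
  if (config$learning_zero_reward_trials_per_shape >
      config$learning_trials_per_shape) {
    fail("zero-reward trials per shape exceed trials per shape")
  }
  if (config$learning_zero_reward_trials_per_shape < 0L) {
    fail("zero-reward count must be non-negative")
  }
  if (config$ssd_step_ms <= 0) fail("ssd_step_ms must be positive")
  if (config$ssd_floor_ms > config$ssd_ceiling_ms) {
    fail("ssd_floor_ms exceeds ssd_ceiling_ms")
  }
  if (config$ssd_initial_ms < config$ssd_floor_ms ||
      config$ssd_initial_ms > config$ssd_ceiling_ms) {
    fail("ssd_initial_ms outside [floor, ceiling]")
  }
  if (config$auction_presentations_per_shape !=
      2L * length(config$bid_sets)) {
    fail("auction presentations per shape must equal 2 x number of bid sets")
  }
  if (config$reward_dispersion_cents < 0L) fail("dispersion must be >= 0")
  if (config$response_deadline_ms <= 0) fail("deadline must be positive")
  invisible(config)
}

#' Write / read a study configuration
#'
#' Configurations serialize to JSON or YAML (chosen by file extension) and
#' round-trip losslessly.
#'
#' @param config A `study_config`.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a validated `study_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  ext <- tolower(tools::file_ext(path))
  payload <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  if (is.matrix(raw$bid_sets) || is.data.frame(raw$bid_sets)) {
    sets <- as.matrix(raw$bid_sets)
    raw$bid_sets <- lapply(seq_len(nrow(sets)),
                           function(i) unname(sets[i, ]))
  }
  do.call(study_config, raw)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  learning : %d trials/shape (%d zero-reward), %d blocks\n",
              x$learning_trials_per_shape,
              x$learning_zero_reward_trials_per_shape, x$learning_blocks))
  cat(sprintf("  treatment: %d trials/shape, stop fraction %.2f, %d blocks\n",
              x$treatment_trials_per_shape, x$stop_fraction_on_stop_shapes,
              x$treatment_blocks))
  cat(sprintf("  auction  : %d presentations/shape over %d bid sets, %d blocks\n",
              x$auction_presentations_per_shape, length(x$bid_sets),
              x$auction_blocks))
  cat(sprintf("  values   : %s cents (+/- %d); SSD start %g step %g ms\n",
              paste(x$value_means_cents, collapse = "/"),
              x$reward_dispersion_cents, x$ssd_initial_ms, x$ssd_step_ms))
  invisible(x)
}

# Run code under a fixed seed when one is supplied, otherwise use the
# ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
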