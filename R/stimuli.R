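#' Shape and color inventories
#'
#' The eight geometric shapes and eight colors used to build participant-
#' specific stimuli. Shape-color pairings, value levels and stop-pairing are
#' randomized per participant by [assign_stimuli()].
#'
#' @return Character vector of length 8.
#' @export
shape_names <- function() {
  c("square", "circle", "diamond", "triangle",
    "inverted_triangle", "cross", "hexagon", "i_shape")
}

#' @rdname shape_names
#' @export
color_names <- function() {
  c("white", "green", "blue", "yellow", "cyan", "magenta", "orange", "gray")
}

#' Randomly assign stimuli to values and stop-pairing
#'
#' Builds the eight participant-specific stimuli: each shape is paired with
#' a unique color, the eight shape-color compounds are assigned in pairs to
#' the four value levels, and within every value level exactly one of the
#' two stimuli is designated stop-paired (it will carry stop signals in the
#' treatment phase; the other never will).
#'
#' @param config A `study_config` supplying the four value means.
#' @param rng_seed Optional integer seed; the assignment is a pure function
#'   of the seed.
#'
#' @return A tibble with one row per stimulus and columns `stimulus_id`
#'   (e.g. `"green_square"`), `shape`, `color`, `value_level` (1-4),
#'   `mean_value_cents`, and `stop_paired`.
#' @export
assign_stimuli <- function(config = cohort_preset(), rng_seed = NULL) {
  validate_config(config)
  with_seed_if(rng_seed, {
    shapes <- sample(shape_names())
    colors <- sample(color_names())
    # pair i-th shuffled shape with i-th shuffled color, then deal the eight
    # compounds to value levels 1..4 (two each) in shuffled order
    level <- sample(rep(1:4, each = 2L))
    stop_paired <- logical(8L)
    for (lv in 1:4) {
      members <- which(level == lv)
      stop_paired[sample(members, 1L)] <- TRUE
    }
    tibble::tibble(
      stimulus_id = paste(colors, shapes, sep = "_"),
      shape = shapes,
      color = colors,
      value_level = as.integer(level),
      mean_value_cents = config$value_means_cents[level],
      stop_paired = stop_paired
    )
  })
}

# Structural check used by schedule generators and the simulator.
validate_stimuli <- function(stimuli) {
  stopifnot(is.data.frame(stimuli), nrow(stimuli) == 8L)
  if (anyDuplicated(stimuli$shape) || anyDuplicated(stimuli$color)) {
    stop("each shape and color must be used exactly once", call. = FALSE)
  }
  counts <- table(factor(stimuli$value_level, levels = 1:4))
  if (any(counts != 2L)) {
    stop("each value level must have exactly 2 stimuli", call. = FALSE)
  }
  sp <- tapply(stimuli$stop_paired, stimuli$value_level, sum)
  if (any(sp != 1L)) {
    stop("each value level must have exactly 1 stop-paired stimulus",
         call. = FALSE)
  }
  invisible(stimuli)
}
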