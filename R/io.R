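#' Write a simulated dataset to disk
#'
#' Emits the documented plain-text artifact layout: `config.json`,
#' `stimuli.csv`, `learning.csv`, `treatment.csv`, `auction.csv`,
#' `ground_truth.csv`, `debriefs.json`, and a `manifest.json` recording the
#' seed, package version, and the MD5 checksum of every emitted file.
#'
#' @param dataset A `devalsim_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "devalsim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(dataset$config, file.path(dir, "config.json"))
  for (name in c("stimuli", "learning", "treatment", "auction",
                 "ground_truth")) {
    write_trials(dataset[[name]], file.path(dir, paste0(name, ".csv")))
  }
  jsonlite::write_json(
    lapply(dataset$debriefs, unclass),
    file.path(dir, "debriefs.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  files <- c("config.json", "stimuli.csv", "learning.csv", "treatment.csv",
             "auction.csv", "ground_truth.csv", "debriefs.json")
  manifest <- list(
    package = "devalsim",
    version = as.character(utils::packageVersion("devalsim")),
    rng_seed = dataset$rng_seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(files, files), function(f) {
      list(path = f,
           md5 = unname(tools::md5sum(file.path(dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' Verifies the manifest checksums (if a manifest is present) and rebuilds
#' the `devalsim_dataset` structure losslessly.
#'
#' @param dir Directory containing the artifact files.
#' @return A `devalsim_dataset`.
#' @export
read_dataset <- function(dir) {
  need <- c("config.json", "stimuli.csv", "learning.csv", "treatment.csv",
            "auction.csv", "ground_truth.csv", "debriefs.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing dataset input(s) in ", dir, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  manifest_path <- file.path(dir, "manifest.json")
  seed <- NULL
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
    seed <- manifest$rng_seed
    for (entry in manifest$files) {
      actual <- unname(tools::md5sum(file.path(dir, entry$path)))
      if (!identical(actual, entry$md5)) {
        stop("checksum mismatch for ", entry$path, call. = FALSE)
      }
    }
  }
  debriefs_raw <- jsonlite::read_json(file.path(dir, "debriefs.json"),
                                      simplifyVector = FALSE)
  debriefs <- lapply(debriefs_raw, function(d) {
    named <- if (length(d$named_shapes)) {
      data.frame(
        stimulus_id = vapply(d$named_shapes, `[[`, character(1),
                             "stimulus_id"),
        claimed_value_level = vapply(d$named_shapes, function(x)
          as.integer(x$claimed_value_level), integer(1))
      )
    } else {
      data.frame(stimulus_id = character(), claimed_value_level = integer())
    }
    structure(
      list(
        reported_contingency_feeling = isTRUE(d$reported_contingency_feeling),
        named_shapes = named,
        noticed_stop_pairing = isTRUE(d$noticed_stop_pairing)
      ),
      class = "simulated_debrief"
    )
  })
  structure(
    list(
      config = read_config(file.path(dir, "config.json")),
      rng_seed = if (!is.null(seed)) as.integer(seed),
      stimuli = read_trials(file.path(dir, "stimuli.csv")),
      learning = read_trials(file.path(dir, "learning.csv")),
      treatment = read_trials(file.path(dir, "treatment.csv")),
      auction = read_trials(file.path(dir, "auction.csv")),
      debriefs = debriefs,
      ground_truth = read_trials(file.path(dir, "ground_truth.csv"))
    ),
    class = "devalsim_dataset"
  )
}
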