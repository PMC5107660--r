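#' Default run configuration
#'
#' The full set of engine and image-pipeline settings with their standard
#' values: 32-patch grid, 30000 seeded cells with 95% attachment, threshold
#' `n_crit = 5`, coupling factor 1.9, unit substrate deposit, 80 time steps
#' recorded every 10, dual image thresholds 125/85 with the 300-px mask
#' floor and 20-px nucleus ceiling.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    hypothesis = 1L,
    grid_size = 32L,
    n_cells = 30000L,
    engraft_prob = 0.95,
    n_steps = 80L,
    record_every = 10L,
    replicates = 30L,
    n_crit = 5,
    c_envfactor = 1.9,
    c_amount = 1,
    c_formula_scale = 20,
    c_formula_divisor = 21.2,
    max_target_neighbors = 6L,
    movement_threshold = 1,
    seeding_mode = "instant_cull",
    substrate_deposit_mode = "once",
    threshold = 125,
    threshold_inside = 85,
    mask_min_size = 300L,
    nucleus_max_size = 20L,
    connectivity = 8L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills unset keys with [default_config()]
#' values, and rejects unknown keys by name. An empty file yields the pure
#' default configuration.
#'
#' @param path YAML file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, user)
}

#' @rdname load_config
#' @param config Configuration list to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Rule set described by a configuration
#'
#' @param config A configuration list from [load_config()].
#' @return A `ruleset` ([hypothesis1()] or [hypothesis2()]) with the
#'   config's `n_crit`, `c_envfactor`, `c_amount` and crowding limit.
#' @export
config_ruleset <- function(config) {
  rs <- if (identical(as.integer(config$hypothesis), 2L)) {
    hypothesis2()
  } else {
    hypothesis1()
  }
  rs$n_crit <- config$n_crit
  rs$c_envfactor <- config$c_envfactor
  rs$c_amount <- config$c_amount
  rs$max_target_neighbors <- config$max_target_neighbors
  rs
}

#' Write / read a slice trajectory as CSV
#'
#' Long format, one row per (replicate,) time step and slice, with columns
#' `n_cells` and `cvhv`; write-then-read round-trips the table.
#'
#' @param trajectory Non-empty trajectory tibble.
#' @param path Output CSV path.
#' @return `path` invisibly; the reader returns a tibble.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  if (is.null(trajectory) || nrow(trajectory) == 0) {
    abort("cannot write an empty trajectory")
  }
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("replicate" %in% names(out)) {
    class(out) <- c("engraftment_trajectory", class(out))
  }
  out
}

#' Write a run manifest
#'
#' Records everything needed to re-run an experiment bit-identically: the
#' configuration snapshot and its hash, the seed(s), the package version, a
#' timestamp, and the output file list.
#'
#' @param dir Output directory (created if missing).
#' @param config Configuration list.
#' @param seed Seed(s) used.
#' @param outputs Character vector of output files.
#' @return Path of the written manifest, invisibly.
#' @export
write_run_manifest <- function(dir, config, seed, outputs = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "recell",
    version = as.character(utils::packageVersion("recell")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    config_hash = rlang::hash(config),
    outputs = outputs
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
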