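#' Run the scaffold-engraftment simulation
#'
#' Seeds `n_cells` agents on distinct random patches of the `grid_size^3`
#' scaffold lattice, then iterates the behavioral rules for `n_steps` time
#' steps. Within each step every agent acts once, in a freshly randomized
#' order: motile cells re-orient and move (chemotactically when the weighted
#' substrate signal ahead exceeds `movement_threshold`, randomly otherwise)
#' and attempt to attach; engrafted cells age, die when their age counter
#' reaches their drawn lifespan, and place one offspring on an uncrowded
#' unoccupied neighbor patch when their proliferation counter reaches its
#' delay. Engrafted cells deposit substrate on their patch and the deposit
#' decays at death.
#'
#' At seeding each agent attaches with probability `engraft_prob`. Under the
#' default `seeding_mode = "instant_cull"` the non-attachers are eliminated
#' immediately; under `"one_step_grace"` they stay motile for one full time
#' step (moving and re-attempting attachment) and are eliminated at its end.
#'
#' Every `record_every` steps the engrafted cells in 30 fixed interior
#' z-planes (configurable via `slice_z`) are counted per slice, and the CVHV
#' of each slice is computed from the bounded Voronoi tessellation of the
#' in-plane cell coordinates (see [cvhv()]); slices with fewer than two
#' cells record `NA`.
#'
#' @param rules A [new_ruleset()] object ([hypothesis1()] / [hypothesis2()]).
#' @param n_steps Number of time steps (default 80).
#' @param seed Integer seed; if given, the run is bit-reproducible.
#' @param n_cells Number of seeded agents (default 30000).
#' @param engraft_prob Per-agent attachment probability at seeding (0.95).
#' @param grid_size Patches per axis (default 32).
#' @param record_every Recording interval in steps (default 10). Ignored if
#'   `record_steps` is given.
#' @param record_steps Integer vector of steps at which to record slices.
#' @param slice_z z-coordinates of the recorded slices; default the 30
#'   interior planes (-15 .. 14 on the default grid).
#' @param compute_cvhv Compute per-slice CVHV at recording times (default
#'   TRUE; turn off when only counts are needed).
#' @param keep_positions Keep engrafted-cell coordinates at each recording
#'   time (for [extract_slice()] and re-analysis).
#' @param seeding_mode `"instant_cull"` (default) or `"one_step_grace"`.
#' @param substrate_deposit_mode `"once"` (default: one deposit at
#'   engraftment, one decay at death) or `"per_step"` (deposit every step a
#'   cell is alive).
#' @param movement_threshold Signal sum above which a motile cell moves
#'   toward the strongest ahead patch (default 1).
#' @param proliferation Set `FALSE` to disable proliferation (pure
#'   survival cohort, used for calibration checks).
#' @param c_formula_scale,c_formula_divisor Constants of the baseline
#'   substrate field (20 and 21.2).
#' @return An object of class `engraftment_sim`: a list with elements
#'   `trajectory` (tibble: `time_step`, `slice`, `n_cells`, `cvhv`),
#'   `totals` (per-step tibble of engrafted/motile counts, attachments,
#'   births, deaths), `engrafted_t0`, `positions` (if kept), `substrate`
#'   (final field), `rules`, `seed` and `config`.
#' @export
#' @examples
#' sim <- simulate_engraftment(hypothesis1(),
#'   n_steps = 10, seed = 1,
#'   n_cells = 2000, compute_cvhv = FALSE
#' )
#' head(sim$trajectory)
simulate_engraftment <- function(rules, n_steps = 80, seed = NULL,
                                 n_cells = 30000, engraft_prob = 0.95,
                                 grid_size = 32, record_every = 10,
                                 record_steps = NULL, slice_z = NULL,
                                 compute_cvhv = TRUE, keep_positions = FALSE,
                                 seeding_mode = c("instant_cull", "one_step_grace"),
                                 substrate_deposit_mode = c("once", "per_step"),
                                 movement_threshold = 1, proliferation = TRUE,
                                 c_formula_scale = 20, c_formula_divisor = 21.2) {
  stopifnot(inherits(rules, "ruleset"), n_steps >= 1, n_cells >= 0,
            engraft_prob >= 0, engraft_prob <= 1)
  seeding_mode <- match.arg(seeding_mode)
  substrate_deposit_mode <- match.arg(substrate_deposit_mode)
  if (n_cells > grid_size^3) {
    abort("n_cells exceeds the number of patches in the lattice")
  }
  if (is.null(record_steps)) {
    record_steps <- if (n_steps >= record_every) {
      seq.int(record_every, n_steps, by = record_every)
    } else {
      n_steps
    }
  }
  record_steps <- sort(unique(as.integer(record_steps)))
  stopifnot(all(record_steps >= 1), all(record_steps <= n_steps))
  if (is.null(slice_z)) {
    co <- lattice_coords(grid_size)
    slice_z <- co[co >= -grid_size / 2 + 1 & co <= grid_size / 2 - 2]
    if (length(slice_z) > 30) {
      slice_z <- slice_z[seq_len(30) + (length(slice_z) - 30) %/% 2]
    }
  }
  check_in_lattice(0, 0, slice_z, grid_size)

  spec_for_engine <- function(s) {
    list(kind = if (s$kind == "coupled") 1L else 0L, lo = s$lo, hi = s$hi,
         base = s$base, sign = s$sign, scale = s$scale)
  }
  cfg <- list(
    grid_size = as.integer(grid_size), n_cells = as.integer(n_cells),
    engraft_prob = engraft_prob, n_steps = as.integer(n_steps),
    record_steps = as.integer(record_steps), slice_z = as.integer(slice_z),
    seeding_grace = seeding_mode == "one_step_grace",
    compute_cvhv = compute_cvhv, keep_positions = keep_positions,
    c_formula_scale = c_formula_scale, c_formula_divisor = c_formula_divisor,
    n_crit = rules$n_crit, c_envfactor = rules$c_envfactor,
    c_amount = rules$c_amount, movement_threshold = movement_threshold,
    per_step_deposit = substrate_deposit_mode == "per_step",
    proliferation = proliferation,
    max_target_neighbors = as.integer(rules$max_target_neighbors),
    init_life = list(kind = 0L, lo = rules$init_life[1], hi = rules$init_life[2]),
    init_prol = list(kind = 0L, lo = rules$init_prol[1], hi = rules$init_prol[2]),
    off_life = spec_for_engine(rules$off_life),
    off_prol = spec_for_engine(rules$off_prol)
  )
  if (!is.null(seed)) set.seed(seed)
  raw <- .cpp_run_engine(cfg)

  traj <- tidyr::expand_grid(
    time_step = as.integer(record_steps),
    slice = as.integer(slice_z)
  )
  traj$n_cells <- as.vector(t(raw$slice_counts))
  traj$cvhv <- as.vector(t(raw$slice_cvhv))

  totals <- as_tibble(raw$totals)
  totals$step <- seq_len(nrow(totals))
  totals <- dplyr::relocate(totals, "step")

  positions <- NULL
  if (keep_positions) {
    positions <- lapply(raw$positions, function(m) {
      tibble(x = m[, 1], y = m[, 2], z = m[, 3])
    })
    names(positions) <- as.character(record_steps)
  }

  structure(
    list(
      trajectory = traj, totals = totals, engrafted_t0 = raw$engrafted_t0,
      positions = positions, substrate = raw$substrate,
      occupancy_violations = raw$occupancy_violations,
      rules = rules, seed = seed, config = cfg
    ),
    class = "engraftment_sim"
  )
}

#' @export
print.engraftment_sim <- function(x, ...) {
  cat("<engraftment_sim> rule set:", x$rules$name, "\n")
  cat("  steps:", x$config$n_steps, " seeded:", x$config$n_cells,
      " engrafted at t=0:", x$engrafted_t0, "\n")
  last <- x$totals$engrafted[nrow(x$totals)]
  cat("  engrafted at final step:", last, "\n")
  invisible(x)
}

#' Replicate runs of the simulation
#'
#' Runs `replicates` independent simulations (seeds derived from `seed`) and
#' stacks their recorded slice trajectories.
#'
#' @inheritParams simulate_engraftment
#' @param replicates Number of independent runs.
#' @param seed Master seed from which per-replicate seeds are drawn.
#' @param ... Passed to [simulate_engraftment()].
#' @return A tibble of class `engraftment_trajectory` with columns
#'   `hypothesis`, `replicate`, `time_step`, `slice`, `n_cells`, `cvhv`.
#' @export
simulate_replicates <- function(rules, replicates = 30, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  out <- purrr::map_dfr(seq_len(replicates), function(i) {
    sim <- simulate_engraftment(rules, seed = seeds[i], ...)
    dplyr::mutate(sim$trajectory,
      hypothesis = rules$name, replicate = i,
      .before = 1
    )
  })
  class(out) <- c("engraftment_trajectory", class(out))
  out
}

#' Per-time-point summary of a slice trajectory
#'
#' Averages slice counts and CVHV over slices (and replicates, if present)
#' at each recorded time step.
#'
#' @param trajectory A tibble with columns `time_step`, `n_cells`, `cvhv`
#'   and optionally `hypothesis`/`replicate`.
#' @param by Additional grouping columns kept in the summary (defaults to
#'   `"hypothesis"` when present).
#' @param cvhv_na How to average CVHV over slices: `"omit"` (drop slices
#'   whose CVHV is undefined) or `"zero"` (a slice with fewer than two
#'   cells has no clustering heterogeneity and contributes 0 -- the
#'   convention for population-level mean trajectories near extinction).
#' @return A tibble with `mean_n_cells`, `se_n_cells`, `mean_cvhv`,
#'   `se_cvhv` per time step (and group).
#' @export
summarize_trajectory <- function(trajectory,
                                 by = intersect("hypothesis", names(trajectory)),
                                 cvhv_na = c("omit", "zero")) {
  cvhv_na <- match.arg(cvhv_na)
  if (cvhv_na == "zero" && "cvhv" %in% names(trajectory)) {
    trajectory$cvhv <- ifelse(
      is.na(trajectory$cvhv) & trajectory$n_cells < 2, 0, trajectory$cvhv
    )
  }
  grp <- c(by, "time_step")
  trajectory |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_n_cells = mean(.data$n_cells, na.rm = TRUE),
      se_n_cells = sd(.data$n_cells, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$n_cells))),
      mean_cvhv = mean(.data$cvhv, na.rm = TRUE),
      se_cvhv = sd(.data$cvhv, na.rm = TRUE) / sqrt(sum(!is.na(.data$cvhv))),
      .groups = "drop"
    )
}

#' Extract one 2D slice of cell positions
#'
#' @param positions A data frame of 3D cell coordinates with columns `x`,
#'   `y`, `z` (e.g. one element of `sim$positions`).
#' @param axis Axis perpendicular to the slice (`"x"`, `"y"` or `"z"`).
#' @param index Lattice coordinate of the slice along `axis`.
#' @param grid_size Patches per axis (bounds check).
#' @return A tibble of the two in-plane coordinate columns.
#' @export
extract_slice <- function(positions, axis = c("z", "x", "y"), index,
                          grid_size = 32) {
  axis <- match.arg(axis)
  stopifnot(all(c("x", "y", "z") %in% names(positions)), length(index) == 1)
  lo <- -grid_size / 2
  hi <- grid_size / 2 - 1
  if (index < lo || index > hi) {
    abort(sprintf("slice index %s outside lattice bounds [%d, %d]", index, lo, hi))
  }
  keep <- setdiff(c("x", "y", "z"), axis)
  positions |>
    dplyr::filter(.data[[axis]] == index) |>
    dplyr::select(dplyr::all_of(keep)) |>
    as_tibble()
}

#' Map simulation units onto physical units
#'
#' Relates lattice/step units to physical scales: a slice of `grid_size`
#' patches spans `scaffold_width_um` micrometres, and `n_steps` time steps
#' span `duration_days` days. With the defaults (32 patches over 1000 um,
#' 80 steps over 28 days) a patch is ~31 um across, one patch-per-step
#' motion corresponds to a rate of ~0.002 time steps per minute, i.e. a cell
#' velocity of ~0.06 um/min.
#'
#' @param grid_size Patches per axis of a slice.
#' @param scaffold_width_um Physical width of the modeled slice, um.
#' @param n_steps Time steps spanning the experiment.
#' @param duration_days Physical duration, days.
#' @return A one-row tibble: `patch_size_um`, `step_rate_per_min`,
#'   `velocity_um_per_min`.
#' @export
#' @examples
#' calibrate_time_scale(32, 1000, 80, 28)
calibrate_time_scale <- function(grid_size = 32, scaffold_width_um = 1000,
                                 n_steps = 80, duration_days = 28) {
  vals <- c(grid_size, scaffold_width_um, n_steps, duration_days)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all calibration inputs must be positive")
  }
  patch <- scaffold_width_um / grid_size
  minutes <- duration_days * 24 * 60
  rate <- n_steps / minutes
  tibble(
    patch_size_um = patch,
    step_rate_per_min = rate,
    velocity_um_per_min = patch * rate
  )
}
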