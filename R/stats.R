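#' Normalize a trajectory to its first recorded value
#'
#' Expresses each value as a percentage of the first value of the series,
#' so every normalized series starts at 100. Normalizing twice is a no-op.
#'
#' @param values Numeric series ordered by time; the first element must be
#'   nonzero.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' normalize_trajectory(c(200, 100, 50)) # 100 50 25
normalize_trajectory <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (is.na(values[1]) || values[1] == 0) {
    abort("first recorded value must be nonzero to normalize")
  }
  100 * values / values[1]
}

# per-replicate slice means, optionally normalized to the first time point
replicate_means <- function(trajectory, response, normalize) {
  grp <- intersect(c("hypothesis", "replicate"), names(trajectory))
  out <- trajectory |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "time_step")))) |>
    dplyr::summarise(
      value = mean(.data[[response]], na.rm = TRUE),
      .groups = "drop_last"
    ) |>
    dplyr::arrange(.data$time_step, .by_group = TRUE)
  if (normalize) {
    out <- dplyr::mutate(out, value = normalize_trajectory(.data$value))
  }
  dplyr::ungroup(out)
}

#' Compare two rule sets by two-way ANOVA on trajectories
#'
#' Reduces a replicate slice trajectory (see [simulate_replicates()]) to one
#' value per replicate and time point (the mean over slices), normalizes
#' each replicate's series to its first recorded time point (percent scale,
#' as the trajectories are presented), and fits a fixed-effects two-way
#' ANOVA with factors group (rule set) and time, type-II sums of squares.
#' The headline result is the group main-effect p-value.
#'
#' @param trajectory A tibble with columns `hypothesis`, `replicate`,
#'   `time_step`, and the response column (typically the row-bound output
#'   of two [simulate_replicates()] calls).
#' @param response `"n_cells"` (default) or `"cvhv"`.
#' @param normalize Normalize each replicate series to its first time point
#'   (default TRUE).
#' @return An object of class `hypothesis_comparison` with [tidy()] and
#'   [glance()] methods; `glance()` reports the group effect.
#' @export
compare_hypotheses <- function(trajectory, response = c("n_cells", "cvhv"),
                               normalize = TRUE) {
  response <- match.arg(response)
  stopifnot(all(c("hypothesis", "replicate", "time_step") %in% names(trajectory)))
  if (length(unique(trajectory$hypothesis)) < 2) {
    abort("need at least two groups in `hypothesis` to compare")
  }
  dat <- replicate_means(trajectory, response, normalize)
  dat$group <- factor(dat$hypothesis)
  dat$time <- factor(dat$time_step)
  counts <- table(dat$group, dat$time)
  if (any(counts == 0)) abort("empty group x time cells in the design")
  fit <- lm(value ~ group + time, data = dat)
  an <- car::Anova(fit, type = 2)
  tab <- tibble(
    term = rownames(an),
    sumsq = an[["Sum Sq"]],
    df = an[["Df"]],
    statistic = an[["F value"]],
    p_value = an[["Pr(>F)"]]
  )
  structure(
    list(model = fit, anova = tab, data = dat, response = response,
         normalized = normalize),
    class = "hypothesis_comparison"
  )
}

#' @export
print.hypothesis_comparison <- function(x, ...) {
  g <- glance(x)
  cat("<hypothesis_comparison> response:", x$response,
      if (x$normalized) "(normalized to first time point)" else "(raw)", "\n")
  cat(sprintf("  group effect: F = %.3f, p = %.3g\n", g$statistic, g$p_value))
  invisible(x)
}

#' @rdname compare_hypotheses
#' @param x A `hypothesis_comparison` object.
#' @param ... Unused.
#' @export
tidy.hypothesis_comparison <- function(x, ...) {
  x$anova
}

#' @rdname compare_hypotheses
#' @export
glance.hypothesis_comparison <- function(x, ...) {
  row <- x$anova[x$anova$term == "group", ]
  tibble(
    statistic = row$statistic, p_value = row$p_value, df = row$df,
    response = x$response, normalized = x$normalized
  )
}

#' Parameter sensitivity of the clustering metric
#'
#' Perturbs each model parameter in turn by `+delta` and `-delta` (default
#' +/-5%) at the beginning of the simulation, runs `replicates` independent
#' simulations per condition, measures the CVHV (mean over recorded slices)
#' at `probe_step`, and tests each perturbed condition against the
#' unperturbed control by one-way ANOVA at `alpha`. The probe step should
#' sit where the engrafted population is collapsing (step 40 under the
#' short-lived rule set, 50 under the long-lived one), where parameter
#' changes have had time to act.
#'
#' @param rules Baseline [new_ruleset()].
#' @param probe_step Time step at which CVHV is measured.
#' @param parameters Parameters to perturb (default all five).
#' @param delta Relative perturbation (default 0.05).
#' @param replicates Runs per condition (default 30).
#' @param seed Master seed.
#' @param alpha Significance level (default 0.05).
#' @param ... Passed to [simulate_engraftment()] (e.g. `n_cells`).
#' @return A tibble of class `sensitivity_report`: one row per condition
#'   (`parameter`, `direction`, `mean_cvhv`, `se_cvhv`, `p_value`,
#'   `significant`), control row first; attribute `values` holds the
#'   per-replicate measurements.
#' @export
sensitivity_analysis <- function(rules, probe_step,
                                 parameters = c("n_crit", "c_amount",
                                                "c_envfactor", "t_life",
                                                "t_prol"),
                                 delta = 0.05, replicates = 30, seed = NULL,
                                 alpha = 0.05, ...) {
  stopifnot(inherits(rules, "ruleset"), probe_step >= 1, replicates >= 2)
  parameters <- match.arg(parameters, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)

  measure <- function(rs) {
    seeds <- sample.int(.Machine$integer.max - 1L, replicates)
    purrr::map_dbl(seeds, function(s) {
      sim <- simulate_engraftment(rs,
        n_steps = probe_step, seed = s,
        record_steps = probe_step, compute_cvhv = TRUE, ...
      )
      tr <- sim$trajectory
      # slices with < 2 cells carry no clustering heterogeneity
      mean(ifelse(is.na(tr$cvhv) & tr$n_cells < 2, 0, tr$cvhv), na.rm = TRUE)
    })
  }

  control <- measure(rules)
  rows <- list(tibble(
    parameter = "control", direction = "0",
    mean_cvhv = mean(control, na.rm = TRUE),
    se_cvhv = sd(control, na.rm = TRUE) / sqrt(sum(!is.na(control))),
    p_value = NA_real_, significant = NA
  ))
  values <- list(control = control)
  for (p in parameters) {
    for (dir in c(1, -1)) {
      rs <- perturb_ruleset(rules, p, dir * delta)
      v <- measure(rs)
      dat <- data.frame(
        value = c(control, v),
        grp = factor(rep(c("control", "perturbed"), c(length(control), length(v))))
      )
      dat <- dat[!is.na(dat$value), ]
      pv <- summary(aov(value ~ grp, data = dat))[[1]][["Pr(>F)"]][1]
      lab <- sprintf("%s%s", if (dir > 0) "+" else "-",
                     format(100 * delta))
      rows <- c(rows, list(tibble(
        parameter = p, direction = paste0(lab, "%"),
        mean_cvhv = mean(v, na.rm = TRUE),
        se_cvhv = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))),
        p_value = pv, significant = pv < alpha
      )))
      values[[paste(p, lab, sep = "")]] <- v
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "values") <- values
  attr(out, "probe_step") <- probe_step
  attr(out, "ruleset") <- rules$name
  attr(out, "alpha") <- alpha
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' @rdname sensitivity_analysis
#' @param x A `sensitivity_report`.
#' @export
tidy.sensitivity_report <- function(x, ...) {
  as_tibble(as.data.frame(x))
}
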