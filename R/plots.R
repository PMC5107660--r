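#' Plot replicate trajectories
#'
#' Mean with standard-error ribbon of the chosen response over time, one
#' series per rule set.
#'
#' @param object An `engraftment_trajectory` tibble from
#'   [simulate_replicates()] (possibly several row-bound rule sets).
#' @param response `"n_cells"` or `"cvhv"`.
#' @param normalize Normalize each replicate series to its first recorded
#'   time point (percent scale).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.engraftment_trajectory <- function(object,
                                            response = c("n_cells", "cvhv"),
                                            normalize = TRUE, ...) {
  response <- match.arg(response)
  dat <- replicate_means(object, response, normalize)
  grp <- if ("hypothesis" %in% names(dat)) "hypothesis" else NULL
  summ <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "time_step")))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      .groups = "drop"
    )
  lab <- if (response == "n_cells") "engrafted cells per slice" else "CVHV"
  if (normalize) lab <- paste0(lab, " (% of first time point)")
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_step, y = .data$mean))
  if (!is.null(grp)) {
    p <- p + ggplot2::aes(colour = .data$hypothesis, fill = .data$hypothesis)
  }
  p +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time step", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a bounded Voronoi tessellation
#'
#' @param object A [voronoi_tessellate()] result (with polygons kept).
#' @param ... Unused.
#' @return A ggplot object: tiles colored by area, sites overplotted.
#' @export
autoplot.voronoi_tessellation <- function(object, ...) {
  if (is.null(object$polygons)) {
    abort("tessellation was computed with polygons = FALSE")
  }
  polys <- purrr::imap_dfr(object$polygons, function(m, i) {
    tibble(tile = i, x = m[, 1], y = m[, 2], area = object$areas[i])
  })
  ggplot2::ggplot(polys, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(
      ggplot2::aes(group = .data$tile, fill = .data$area),
      colour = "grey30", linewidth = 0.2
    ) +
    ggplot2::geom_point(
      data = object$points, size = 0.6, colour = "black"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = "tile area")
}

#' Plot a sensitivity report
#'
#' Bar chart of mean CVHV per perturbed condition with standard-error bars;
#' the unperturbed control is leftmost and conditions that differ
#' significantly from it are starred.
#'
#' @param object A [sensitivity_analysis()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  dat <- tidy(object)
  dat$label <- ifelse(dat$parameter == "control", "control",
                      paste0(dat$parameter, " ", dat$direction))
  dat$label <- factor(dat$label, levels = dat$label)
  dat$mark <- dplyr::case_when(
    is.na(dat$significant) ~ "",
    dat$significant ~ "*",
    TRUE ~ "NS"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$mean_cvhv)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey20") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_cvhv - .data$se_cvhv,
        ymax = .data$mean_cvhv + .data$se_cvhv
      ),
      width = 0.3
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$mark, y = .data$mean_cvhv + 1.8 * .data$se_cvhv),
      vjust = 0
    ) +
    ggplot2::labs(
      x = NULL, y = sprintf("CVHV at step %d", attr(object, "probe_step")),
      title = attr(object, "ruleset")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Display a micrograph with optional detected centroids
#'
#' @param image Grayscale matrix (0-255).
#' @param centroids Optional `centroid_set` or data frame with `row`, `col`.
#' @return A ggplot object.
#' @export
plot_micrograph <- function(image, centroids = NULL) {
  img <- to_grayscale(image)
  dat <- tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = as.vector(img)
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::guides(fill = "none")
  if (!is.null(centroids)) {
    pts <- if (inherits(centroids, "centroid_set")) centroids$points else centroids
    p <- p + ggplot2::geom_point(
      data = pts, colour = "red", shape = 3, size = 1.5
    )
  }
  p
}
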