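#' Specification for a synthetic micrograph
#'
#' Describes a stained-slice-like test image with known ground truth: small
#' dark nucleus discs, large dark clumps (mask regions) containing darker
#' sub-nuclei, and mid-sized debris detectable by neither rule, all on a
#' light background. The default intensities (background 230, nuclei 60,
#' clump body 110) are chosen so the 125/85 dual thresholds exercise both
#' detection branches: clump bodies fall below 125 (mask-forming) but above
#' 85, while nuclei fall below both.
#'
#' @param image_size `c(rows, cols)` in pixels.
#' @param n_nuclei Number of isolated nuclei.
#' @param nucleus_radius Nucleus disc radius, px; the default 2 gives
#'   13-pixel discs, under the 20-px detection ceiling.
#' @param n_clumps Number of large clump regions.
#' @param clump_radius Clump disc radius, px; the default 12 gives ~440 px,
#'   over the 300-px mask floor.
#' @param clump_nuclei Dark sub-nuclei per clump (detected in-mask).
#' @param n_debris Number of debris blobs (too big for nuclei, too small
#'   for masks).
#' @param debris_radius Debris radius, px (default 4: ~49 px).
#' @param background_intensity,nucleus_intensity,clump_intensity 8-bit
#'   intensities.
#' @param noise_sd Additive Gaussian intensity noise (default 0).
#' @param clustering Optional within-cluster dispersion (px) for nucleus
#'   placement; `NULL` places nuclei uniformly.
#' @param n_clusters Cluster count when `clustering` is set.
#' @param seed Seed for reproducible generation.
#' @return A list of class `fixture_spec`.
#' @export
micrograph_spec <- function(image_size = c(256, 256), n_nuclei = 40,
                            nucleus_radius = 2, n_clumps = 0,
                            clump_radius = 12, clump_nuclei = 3,
                            n_debris = 0, debris_radius = 4,
                            background_intensity = 230,
                            nucleus_intensity = 60, clump_intensity = 110,
                            noise_sd = 0, clustering = NULL, n_clusters = 5,
                            seed = NULL) {
  structure(as.list(environment()), class = "fixture_spec")
}

draw_disc <- function(img, r0, c0, radius, value) {
  rr <- max(1, floor(r0 - radius)):min(nrow(img), ceiling(r0 + radius))
  cc <- max(1, floor(c0 - radius)):min(ncol(img), ceiling(c0 + radius))
  for (r in rr) {
    for (c in cc) {
      if ((r - r0)^2 + (c - c0)^2 <= radius^2) img[r, c] <- value
    }
  }
  img
}

place_points <- function(n, dim, margin, min_sep, taken, max_tries = 2000) {
  pts <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- c(runif(1, margin, dim[1] - margin), runif(1, margin, dim[2] - margin))
      all_pts <- rbind(taken, pts)
      if (nrow(all_pts) == 0 ||
            min((all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2) >= min_sep^2) {
        pts <- rbind(pts, p)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not place all objects: canvas too crowded for the spec")
    }
  }
  pts
}

#' Generate a synthetic micrograph with known nucleus positions
#'
#' @param spec A [micrograph_spec()].
#' @return A list with `image` (8-bit grayscale matrix) and `truth` (tibble
#'   `row`, `col`, `region` of every placed nucleus center).
#' @export
#' @examples
#' fx <- generate_micrograph(micrograph_spec(n_nuclei = 5, seed = 1))
#' nrow(fx$truth)
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dim <- spec$image_size
  img <- matrix(spec$background_intensity, dim[1], dim[2])
  taken <- matrix(numeric(0), 0, 2)
  truth <- tibble(row = numeric(0), col = numeric(0), region = character(0))

  sep_big <- 2 * spec$clump_radius + 6
  if (spec$n_clumps > 0) {
    clumps <- place_points(spec$n_clumps, dim, spec$clump_radius + 2,
                           sep_big, taken)
    taken <- rbind(taken, clumps)
    for (i in seq_len(nrow(clumps))) {
      img <- draw_disc(img, clumps[i, 1], clumps[i, 2], spec$clump_radius,
                       spec$clump_intensity)
      # darker sub-nuclei inside the clump, kept off the clump rim
      inner <- spec$clump_radius - spec$nucleus_radius - 2
      k <- spec$clump_nuclei
      if (k > 0) {
        # evenly spaced angles keep sub-nuclei from merging into one blob
        ang <- 2 * pi * seq_len(k) / k + runif(1, 0, 2 * pi)
        rad <- inner * (0.55 + 0.4 * seq_len(k) / k)
        for (j in seq_len(k)) {
          r0 <- clumps[i, 1] + rad[j] * sin(ang[j])
          c0 <- clumps[i, 2] + rad[j] * cos(ang[j])
          img <- draw_disc(img, r0, c0, spec$nucleus_radius,
                           spec$nucleus_intensity)
          truth <- dplyr::bind_rows(truth, tibble(row = r0, col = c0,
                                                  region = "inside"))
        }
      }
    }
  }
  if (spec$n_debris > 0) {
    deb <- place_points(spec$n_debris, dim, spec$debris_radius + 2,
                        sep_big, taken)
    taken <- rbind(taken, deb)
    for (i in seq_len(nrow(deb))) {
      img <- draw_disc(img, deb[i, 1], deb[i, 2], spec$debris_radius,
                       spec$nucleus_intensity)
    }
  }
  if (spec$n_nuclei > 0) {
    sep <- max(2 * spec$nucleus_radius + 3, 2)
    margin <- spec$nucleus_radius + 2
    if (is.null(spec$clustering)) {
      nuc <- place_points(spec$n_nuclei, dim, margin,
                          max(sep, spec$clump_radius + 4), taken)
    } else {
      centers <- place_points(spec$n_clusters, dim,
                              margin + 3 * spec$clustering,
                              max(sep_big, 6 * spec$clustering), taken)
      nuc <- matrix(numeric(0), 0, 2)
      for (i in seq_len(spec$n_nuclei)) {
        ok <- FALSE
        for (t in seq_len(2000)) {
          ce <- centers[1 + (i - 1) %% nrow(centers), ]
          p <- ce + rnorm(2, 0, spec$clustering)
          p[1] <- min(max(p[1], margin), dim[1] - margin)
          p[2] <- min(max(p[2], margin), dim[2] - margin)
          all_pts <- rbind(taken, nuc)
          if (nrow(all_pts) == 0 ||
                min((all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2) >= sep^2) {
            nuc <- rbind(nuc, p)
            ok <- TRUE
            break
          }
        }
        if (!ok) abort("could not place all nuclei: reduce n or clustering")
      }
    }
    for (i in seq_len(nrow(nuc))) {
      img <- draw_disc(img, nuc[i, 1], nuc[i, 2], spec$nucleus_radius,
                       spec$nucleus_intensity)
    }
    truth <- dplyr::bind_rows(truth, tibble(row = nuc[, 1], col = nuc[, 2],
                                            region = "outside"))
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img))
    img <- pmin(pmax(round(img), 0), 255)
  }
  list(image = img, truth = truth)
}

#' Generate a planar point pattern with controlled clustering
#'
#' @param n Number of points (at least 2).
#' @param mode `"uniform"` (independent uniform points) or `"clustered"`
#'   (uniform cluster centers with Gaussian-dispersed members).
#' @param dispersion Within-cluster standard deviation (same units as
#'   `bounds`); ignored for `mode = "uniform"`.
#' @param n_clusters Number of cluster centers.
#' @param bounds Rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param seed Seed for reproducibility.
#' @return A tibble with columns `x`, `y`.
#' @export
generate_point_pattern <- function(n, mode = c("uniform", "clustered"),
                                   dispersion = 2, n_clusters = 5,
                                   bounds = c(0, 100, 0, 100), seed = NULL) {
  stopifnot(n >= 2)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  if (mode == "uniform") {
    return(tibble(
      x = runif(n, bounds[1], bounds[2]),
      y = runif(n, bounds[3], bounds[4])
    ))
  }
  cx <- runif(n_clusters, bounds[1], bounds[2])
  cy <- runif(n_clusters, bounds[3], bounds[4])
  idx <- sample.int(n_clusters, n, replace = TRUE)
  x <- cx[idx] + rnorm(n, 0, dispersion)
  y <- cy[idx] + rnorm(n, 0, dispersion)
  # redraw members that fall outside the window (truncated dispersal);
  # clamping instead would pile duplicates onto the boundary
  for (t in 1:200) {
    out <- x < bounds[1] | x > bounds[2] | y < bounds[3] | y > bounds[4]
    if (!any(out)) break
    x[out] <- cx[idx[out]] + rnorm(sum(out), 0, dispersion)
    y[out] <- cy[idx[out]] + rnorm(sum(out), 0, dispersion)
  }
  tibble(
    x = clamp(x, bounds[1], bounds[2]),
    y = clamp(y, bounds[3], bounds[4])
  )
}

#' Render a model slice as a micrograph
#'
#' Converts in-plane cell coordinates (patch units) to a synthetic image the
#' detection pipeline can consume: one dark nucleus disc per cell on a light
#' background, at `scale` pixels per patch.
#'
#' @param points Data frame with columns `x`, `y` in patch units.
#' @param scale Pixels per patch (>= 1; default 8).
#' @param nucleus_radius Disc radius, px.
#' @param bounds Slice rectangle in patch units.
#' @param background_intensity,nucleus_intensity 8-bit intensities.
#' @return A grayscale matrix; attribute `mapping` records `scale` and
#'   `bounds` so detected pixel centroids can be mapped back to patch
#'   coordinates (`x = xmin + col/scale`, `y = ymin + row/scale`).
#' @export
render_slice <- function(points, scale = 8, nucleus_radius = 2,
                         bounds = c(-16.5, 15.5, -16.5, 15.5),
                         background_intensity = 230, nucleus_intensity = 60) {
  stopifnot(scale >= 1)
  w <- ceiling((bounds[2] - bounds[1]) * scale)
  h <- ceiling((bounds[4] - bounds[3]) * scale)
  img <- matrix(background_intensity, h, w)
  for (i in seq_len(nrow(points))) {
    r0 <- (points$y[i] - bounds[3]) * scale
    c0 <- (points$x[i] - bounds[1]) * scale
    img <- draw_disc(img, r0, c0, nucleus_radius, nucleus_intensity)
  }
  attr(img, "mapping") <- list(scale = scale, bounds = bounds)
  img
}
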