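#' Coerce an image to an 8-bit grayscale micrograph
#'
#' A micrograph is a numeric matrix of 8-bit intensities, 0 (black) to 255
#' (white); rows index image rows. RGB(A) arrays are converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B); grayscale input passes through
#' unchanged apart from rescaling. Inputs on the unit scale (all values in
#' \[0, 1\], as returned by PNG/TIFF readers) are rescaled to 0-255.
#'
#' @param image A numeric matrix (grayscale) or 3D array (RGB / RGBA).
#' @return A numeric matrix with values in \[0, 255\].
#' @export
to_grayscale <- function(image) {
  if (length(image) == 0) abort("empty image")
  if (is.array(image) && length(dim(image)) == 3) {
    nch <- dim(image)[3]
    if (nch < 3) {
      image <- image[, , 1]
    } else {
      image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
        0.0722 * image[, , 3]
    }
  }
  if (!is.matrix(image)) abort("image must be a matrix or 3D array")
  img <- image * 1.0
  if (max(img) <= 1 && min(img) >= 0) img <- img * 255
  if (min(img) < 0 || max(img) > 255) {
    abort("intensities must lie in [0, 255] (or [0, 1])")
  }
  img
}

#' Read a PNG or TIFF micrograph
#'
#' @param path Image file (`.png`, `.tif`/`.tiff`), 8-bit grayscale or RGB.
#' @return An 8-bit grayscale matrix (see [to_grayscale()]).
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format: .%s", ext))
  )
  to_grayscale(img)
}

#' Write a grayscale micrograph to PNG
#'
#' @param image Matrix of 8-bit intensities.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

label_sizes <- function(labels) {
  labs <- labels[labels > 0L]
  if (length(labs) == 0) return(integer(0))
  tabulate(labs)
}

component_centroids <- function(labels, keep) {
  if (length(keep) == 0) {
    return(tibble(row = numeric(0), col = numeric(0)))
  }
  sel <- labels > 0L & matrix(labels %in% keep, nrow(labels), ncol(labels))
  labs <- labels[sel]
  rr <- row(labels)[sel]
  cc <- col(labels)[sel]
  sums <- rowsum(cbind(rr, cc), labs)
  n <- as.vector(rowsum(rep(1, length(labs)), labs))
  tibble(row = unname(sums[, 1] / n), col = unname(sums[, 2] / n))
}

#' Detect mask regions (cellular clumps and debris)
#'
#' Thresholds the grayscale image at `threshold` (dark objects: foreground
#' is intensity strictly below the threshold, as hematoxylin-stained nuclei
#' are dark on a light background) and keeps connected components of at
#' least `min_size` pixels. These "mask" regions delimit dense cellular
#' clumps within which nuclei must be re-detected at a lower threshold.
#'
#' @param image Grayscale matrix (0-255); RGB input is converted.
#' @param threshold Intensity threshold (default 125).
#' @param min_size Minimum component size in pixels (default 300).
#' @param connectivity Pixel connectivity, 8 (default) or 4.
#' @return A list of class `mask_set`: `mask` (logical matrix), `components`
#'   (tibble `id`, `size`), `n_masks`.
#' @export
detect_masks <- function(image, threshold = 125, min_size = 300,
                         connectivity = 8) {
  stopifnot(threshold >= 0, threshold <= 255)
  img <- to_grayscale(image)
  fg <- img < threshold
  labels <- .cpp_label_components(fg, as.integer(connectivity))
  sizes <- label_sizes(labels)
  keep <- which(sizes >= min_size)
  mask <- labels > 0L & matrix(labels %in% keep, nrow(labels), ncol(labels))
  structure(
    list(
      mask = mask,
      components = tibble(id = keep, size = sizes[keep]),
      n_masks = length(keep)
    ),
    class = "mask_set"
  )
}

new_centroid_set <- function(points, dim, edit_log = NULL) {
  structure(
    list(
      points = points, n_cells = nrow(points), dim = dim,
      edit_log = edit_log %||%
        tibble(action = character(0), row = numeric(0), col = numeric(0))
    ),
    class = "centroid_set"
  )
}

#' @export
print.centroid_set <- function(x, ...) {
  cat("<centroid_set>", x$n_cells, "nuclei in a", x$dim[1], "x", x$dim[2],
      "image;", nrow(x$edit_log), "manual edits\n")
  invisible(x)
}

#' Detect cell nuclei by dual thresholding
#'
#' Nuclei are small dark connected components (at most `max_size` pixels).
#' Outside the mask regions they are detected at `threshold_outside`; inside
#' the masks -- where nuclei sit on already-dark clump material -- detection
#' is repeated at the stricter `threshold_inside` so that only the darkest
#' sub-objects are marked. Component centroids become the nucleus positions.
#'
#' @param image Grayscale matrix (0-255).
#' @param masks A [detect_masks()] result; computed from `image` with the
#'   default settings if omitted.
#' @param threshold_outside Threshold outside masks (default 125).
#' @param threshold_inside Threshold inside masks (default 85).
#' @param max_size Maximum nucleus component size in pixels (default 20).
#' @param connectivity Pixel connectivity, 8 (default) or 4.
#' @return A `centroid_set`: sub-pixel centroids (`points`: tibble `row`,
#'   `col`, `region`), `n_cells`, image `dim`, and an empty `edit_log`.
#' @export
detect_nuclei <- function(image, masks = NULL, threshold_outside = 125,
                          threshold_inside = 85, max_size = 20,
                          connectivity = 8) {
  stopifnot(
    threshold_outside >= 0, threshold_outside <= 255,
    threshold_inside >= 0, threshold_inside <= 255
  )
  img <- to_grayscale(image)
  if (is.null(masks)) {
    masks <- detect_masks(img, threshold = threshold_outside,
                          connectivity = connectivity)
  }
  stopifnot(inherits(masks, "mask_set"))

  centroids_in <- function(fg) {
    labels <- .cpp_label_components(fg, as.integer(connectivity))
    sizes <- label_sizes(labels)
    component_centroids(labels, which(sizes > 0 & sizes <= max_size))
  }
  outside <- centroids_in(img < threshold_outside & !masks$mask)
  inside <- centroids_in(img < threshold_inside & masks$mask)
  pts <- dplyr::bind_rows(
    dplyr::mutate(outside, region = "outside"),
    dplyr::mutate(inside, region = "inside")
  )
  new_centroid_set(pts, dim(img))
}

#' Programmatic centroid editing
#'
#' The reproducible counterpart of interactive correction: append missed
#' nuclei and delete spurious detections. Every edit is recorded in the
#' centroid set's `edit_log`.
#'
#' @param centroids A `centroid_set` from [detect_nuclei()].
#' @param add Data frame of points to append (columns `row`, `col`).
#' @param remove Data frame of points to delete; each deletes the nearest
#'   existing centroid within `tolerance` pixels.
#' @param tolerance Match radius for removals, pixels (default 2).
#' @return The edited `centroid_set`.
#' @export
edit_centroids <- function(centroids, add = NULL, remove = NULL,
                           tolerance = 2) {
  stopifnot(inherits(centroids, "centroid_set"))
  pts <- centroids$points
  log <- centroids$edit_log
  if (!is.null(add) && nrow(add) > 0) {
    add <- as_tibble(add)
    stopifnot(all(c("row", "col") %in% names(add)))
    if (any(add$row < 1 | add$row > centroids$dim[1] |
              add$col < 1 | add$col > centroids$dim[2])) {
      abort("added points must lie within the image")
    }
    pts <- dplyr::bind_rows(pts, dplyr::mutate(add[, c("row", "col")],
                                               region = "manual"))
    log <- dplyr::bind_rows(log, tibble(action = "add", row = add$row,
                                        col = add$col))
  }
  if (!is.null(remove) && nrow(remove) > 0) {
    remove <- as_tibble(remove)
    stopifnot(all(c("row", "col") %in% names(remove)))
    for (i in seq_len(nrow(remove))) {
      d2 <- (pts$row - remove$row[i])^2 + (pts$col - remove$col[i])^2
      if (length(d2) == 0 || min(d2) > tolerance^2) {
        abort(sprintf(
          "no centroid within %g px of removal point (%.1f, %.1f)",
          tolerance, remove$row[i], remove$col[i]
        ))
      }
      pts <- pts[-which.min(d2), ]
      log <- dplyr::bind_rows(log, tibble(action = "remove",
                                          row = remove$row[i],
                                          col = remove$col[i]))
    }
  }
  new_centroid_set(pts, centroids$dim, log)
}

#' Full image-analysis pipeline: count cells and measure clustering
#'
#' Composes the stages: grayscale conversion, mask detection, dual-threshold
#' nucleus detection, optional programmatic centroid edits, bounded Voronoi
#' tessellation over the image rectangle, and the CVHV clustering metric.
#'
#' @param image Grayscale matrix, RGB array, or a file path (PNG/TIFF).
#' @param threshold,threshold_inside,mask_min_size,nucleus_max_size,connectivity
#'   Detection settings; see [detect_masks()] and [detect_nuclei()].
#' @param edits Optional list with elements `add`, `remove`, `tolerance`
#'   passed to [edit_centroids()].
#' @return A one-row tibble: `n_cells`, `n_masks`, `area_variance`, `cvhv`.
#' @export
analyze_image <- function(image, threshold = 125, threshold_inside = 85,
                          mask_min_size = 300, nucleus_max_size = 20,
                          connectivity = 8, edits = NULL) {
  if (is.character(image)) image <- read_micrograph(image)
  img <- to_grayscale(image)
  masks <- detect_masks(img, threshold = threshold, min_size = mask_min_size,
                        connectivity = connectivity)
  cents <- detect_nuclei(img, masks,
    threshold_outside = threshold,
    threshold_inside = threshold_inside, max_size = nucleus_max_size,
    connectivity = connectivity
  )
  if (!is.null(edits)) {
    cents <- edit_centroids(cents,
      add = edits$add, remove = edits$remove,
      tolerance = edits$tolerance %||% 2
    )
  }
  if (cents$n_cells == 0) {
    abort("no nuclei detected: cannot tessellate an empty point set")
  }
  tess <- voronoi_tessellate(
    tibble(x = cents$points$col, y = cents$points$row),
    bounds = c(0.5, ncol(img) + 0.5, 0.5, nrow(img) + 0.5),
    polygons = FALSE
  )
  tibble(
    n_cells = tess$n,
    n_masks = masks$n_masks,
    area_variance = var(tess$areas),
    cvhv = cvhv(tess)
  )
}
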