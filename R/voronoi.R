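#' Bounded Voronoi tessellation of a planar point set
#'
#' Partitions the bounding rectangle among the points: each point receives
#' the polygonal tile of locations nearer to it than to any other point,
#' with unbounded exterior tiles clipped to the rectangle so every point has
#' a finite territory. Tile areas always sum to the rectangle area.
#'
#' @param points A data frame with numeric columns `x` and `y` (one point
#'   per row), or a two-column matrix.
#' @param bounds Rectangle `c(xmin, xmax, ymin, ymax)`. All points must lie
#'   inside. If `NULL`, the point bounding box padded by 5% per side.
#' @param polygons Keep tile polygons (needed for plotting; default TRUE).
#' @return An object of class `voronoi_tessellation`: list with `points`
#'   (tibble `x`, `y`, `area`), `areas`, `polygons`, `bounds`, `n`.
#' @export
#' @examples
#' tess <- voronoi_tessellate(data.frame(x = c(1, 3), y = c(2, 2)),
#'   bounds = c(0, 4, 0, 4)
#' )
#' tess$areas # two tiles of 8 each
voronoi_tessellate <- function(points, bounds = NULL, polygons = TRUE) {
  if (is.matrix(points)) {
    points <- tibble(x = points[, 1], y = points[, 2])
  }
  stopifnot(all(c("x", "y") %in% names(points)))
  pts <- tibble(x = as.numeric(points$x), y = as.numeric(points$y))
  if (nrow(pts) == 0) {
    abort("cannot tessellate an empty point set")
  }
  if (anyNA(pts)) abort("points contain missing coordinates")
  dup <- duplicated(paste(pts$x, pts$y, sep = "\r"))
  if (any(dup)) {
    warn(sprintf("%d duplicate point(s) merged before tessellation", sum(dup)))
    pts <- pts[!dup, ]
  }
  if (is.null(bounds)) {
    rx <- range(pts$x)
    ry <- range(pts$y)
    padx <- max(diff(rx), 1e-8) * 0.05
    pady <- max(diff(ry), 1e-8) * 0.05
    bounds <- c(rx[1] - padx, rx[2] + padx, ry[1] - pady, ry[2] + pady)
  }
  stopifnot(length(bounds) == 4, bounds[1] < bounds[2], bounds[3] < bounds[4])
  if (any(pts$x < bounds[1] | pts$x > bounds[2] |
            pts$y < bounds[3] | pts$y > bounds[4])) {
    abort("all points must lie within bounds")
  }
  raw <- .cpp_voronoi(pts$x, pts$y, as.numeric(bounds), isTRUE(polygons))
  pts$area <- raw$areas
  structure(
    list(
      points = pts, areas = raw$areas,
      polygons = if (isTRUE(polygons)) raw$polygons else NULL,
      bounds = as.numeric(bounds), n = nrow(pts)
    ),
    class = "voronoi_tessellation"
  )
}

#' @export
print.voronoi_tessellation <- function(x, ...) {
  cat("<voronoi_tessellation>", x$n, "tiles in rectangle [",
      x$bounds[1], ",", x$bounds[2], "] x [", x$bounds[3], ",", x$bounds[4],
      "]\n")
  cat("  total tile area:", sum(x$areas), "\n")
  invisible(x)
}

#' Corrected Voronoi Histogram Variance (CVHV)
#'
#' The variance of the distribution of Voronoi tile areas, multiplied by the
#' number of cells in the image. The multiplication corrects for the fact
#' that, within a fixed field of view, more cells mechanically mean smaller
#' (and less variable) tiles; the product is a cell-count-corrected measure
#' of the spatial heterogeneity of clustering. The sample variance (n - 1
#' denominator) of the tile-area values themselves is used; no histogram
#' binning is involved. Units are (length unit)^4: px^4 for images, patch^4
#' for model slices.
#'
#' @param tess A [voronoi_tessellate()] result, or a numeric vector of tile
#'   areas.
#' @return The CVHV value (>= 0). At least two tiles are required.
#' @export
#' @examples
#' cvhv(c(1, 3)) # sample variance 2, times n = 2 -> 4
cvhv <- function(tess) {
  areas <- if (inherits(tess, "voronoi_tessellation")) tess$areas else tess
  stopifnot(is.numeric(areas))
  if (length(areas) < 2) {
    abort("CVHV requires at least two Voronoi tiles")
  }
  var(areas) * length(areas)
}

#' Count and CVHV of a model-slice point set
#'
#' The coordinate-direct analysis path for simulated slices: tessellates the
#' in-plane cell coordinates within the slice rectangle and reports the cell
#' count and CVHV, mirroring what [analyze_image()] computes for rendered or
#' experimental images.
#'
#' @param points Data frame with columns `x`, `y` (patch units).
#' @param bounds Slice rectangle `c(xmin, xmax, ymin, ymax)`; defaults to
#'   the standard 32-patch slice `c(-16.5, 15.5, -16.5, 15.5)`.
#' @return A one-row tibble: `n_cells`, `area_variance`, `cvhv`.
#' @export
analyze_slice_points <- function(points, bounds = c(-16.5, 15.5, -16.5, 15.5)) {
  tess <- voronoi_tessellate(points, bounds = bounds, polygons = FALSE)
  tibble(
    n_cells = tess$n,
    area_variance = var(tess$areas),
    cvhv = cvhv(tess)
  )
}
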