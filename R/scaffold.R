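#' Lattice coordinate range of the scaffold
#'
#' The scaffold is a cube of `grid_size^3` unit patches with integer patch
#' coordinates running from `-grid_size/2` to `grid_size/2 - 1` on each axis
#' (for the default 32-patch grid: -16 to 15), so that the radial minimum of
#' the substrate field sits at the patch (0, 0).
#'
#' @param grid_size Number of patches per axis (default 32).
#' @return Integer vector of valid patch coordinates for one axis.
#' @export
#' @examples
#' range(lattice_coords())
lattice_coords <- function(grid_size = 32) {
  stopifnot(grid_size >= 2, grid_size %% 2 == 0)
  seq.int(-grid_size / 2, grid_size / 2 - 1)
}

check_in_lattice <- function(x, y, z, grid_size) {
  lo <- -grid_size / 2
  hi <- grid_size / 2 - 1
  bad <- x < lo | x > hi | y < lo | y > hi | z < lo | z > hi
  if (any(bad)) {
    abort(sprintf(
      "coordinates out of lattice bounds [%d, %d]: first offender (%s, %s, %s)",
      lo, hi, x[bad][1], y[bad][1], z[bad][1]
    ))
  }
  invisible(TRUE)
}

#' Baseline substrate concentration at a patch
#'
#' The decellularized scaffold carries a radial gradient of an (unidentified)
#' bioactive substrate: concentration is lowest (zero) on the central axis of
#' each x-y plane and rises toward the scaffold border,
#' `c = scale * sqrt(x^2 + y^2) / divisor`. The field has no z dependence.
#'
#' @param x,y,z Integer patch coordinates (vectorized, recycled).
#' @param scale,divisor Constants of the radial formula (defaults 20 and 21.2).
#' @param grid_size Patches per axis; coordinates are checked against it.
#' @return Numeric vector of concentrations (arbitrary units, >= 0).
#' @export
#' @examples
#' substrate_concentration(0, 0, 5)   # 0 at the central axis
#' substrate_concentration(3, 4, 0)   # 20 * 5 / 21.2
substrate_concentration <- function(x, y, z = 0, scale = 20, divisor = 21.2,
                                    grid_size = 32) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  check_in_lattice(x, y, z, grid_size)
  scale * sqrt(x^2 + y^2) / divisor
}

#' Substrate field over one lattice plane
#'
#' @inheritParams substrate_concentration
#' @param z Plane to evaluate (the field is identical in every plane).
#' @return A tibble with columns `x`, `y`, `z`, `concentration`, one row per
#'   patch of the plane.
#' @export
substrate_field <- function(grid_size = 32, z = 0, scale = 20, divisor = 21.2) {
  coords <- lattice_coords(grid_size)
  grid <- tidyr::expand_grid(x = coords, y = coords)
  dplyr::mutate(grid,
    z = z,
    concentration = substrate_concentration(.data$x, .data$y, z,
      scale = scale, divisor = divisor, grid_size = grid_size
    )
  )
}

#' Neighboring patches of a lattice site
#'
#' All patches within Chebyshev distance 1 of `(x, y, z)` (up to 26), the
#' patch itself excluded. The lattice border is the scaffold edge: there is
#' no wraparound, so corner patches have 7 neighbors and face-interior
#' patches 17.
#'
#' @param x,y,z Integer patch coordinates (scalars).
#' @param grid_size Patches per axis.
#' @return A tibble with columns `x`, `y`, `z`, one row per neighbor.
#' @export
#' @examples
#' nrow(neighbor_coords(0, 0, 0))    # 26
#' nrow(neighbor_coords(-16, -16, -16))  # 7
neighbor_coords <- function(x, y, z, grid_size = 32) {
  stopifnot(length(x) == 1, length(y) == 1, length(z) == 1)
  check_in_lattice(x, y, z, grid_size)
  lo <- -grid_size / 2
  hi <- grid_size / 2 - 1
  nb <- tidyr::expand_grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- dplyr::filter(nb, !(.data$dx == 0 & .data$dy == 0 & .data$dz == 0))
  nb <- dplyr::transmute(nb, x = x + .data$dx, y = y + .data$dy, z = z + .data$dz)
  dplyr::filter(
    nb,
    .data$x >= lo, .data$x <= hi, .data$y >= lo, .data$y <= hi,
    .data$z >= lo, .data$z <= hi
  )
}

#' Substrate bookkeeping at engraftment and death
#'
#' A living engrafted cell raises the substrate concentration of its patch by
#' `amount` (applied once, at engraftment); when the cell dies the deposit
#' decays and the concentration drops by `amount`, floored at zero because
#' concentrations are physical quantities.
#'
#' @param concentration Numeric vector of patch concentrations.
#' @param amount Deposited/decayed amount per event (default 1).
#' @return Updated concentration vector.
#' @export
#' @examples
#' deposit_substrate(4.717)         # 5.717
#' decay_substrate(0.4)             # clamped at 0
deposit_substrate <- function(concentration, amount = 1) {
  stopifnot(amount >= 0)
  concentration + amount
}

#' @rdname deposit_substrate
#' @export
decay_substrate <- function(concentration, amount = 1) {
  stopifnot(amount >= 0)
  pmax(concentration - amount, 0)
}
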