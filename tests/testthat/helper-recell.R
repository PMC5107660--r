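# Shared helpers for the test suite.

# small, fast simulation with sensible test defaults
quick_sim <- function(rules = hypothesis1(), n_steps = 10, seed = 1,
                      n_cells = 2000, ...) {
  simulate_engraftment(rules,
    n_steps = n_steps, seed = seed, n_cells = n_cells,
    compute_cvhv = FALSE, ...
  )
}

# independent tile-area oracle: assign a fine grid of sample points to the
# nearest site; tile area ~ (fraction of grid points) * rectangle area
grid_area_oracle <- function(x, y, bounds, res = 400) {
  gx <- seq(bounds[1], bounds[2], length.out = res)
  gy <- seq(bounds[3], bounds[4], length.out = res)
  pts <- expand.grid(gx = gx, gy = gy)
  d2 <- outer(pts$gx, x, "-")^2 + outer(pts$gy, y, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  counts <- tabulate(nearest, nbins = length(x))
  counts / length(nearest) * (bounds[2] - bounds[1]) * (bounds[4] - bounds[3])
}

# exact rectangle of n_px foreground pixels, top-left at (r0, c0)
paint_block <- function(img, r0, c0, nrow_px, ncol_px, value) {
  img[r0:(r0 + nrow_px - 1), c0:(c0 + ncol_px - 1)] <- value
  img
}

blank_image <- function(nr = 64, nc = 64, value = 230) {
  matrix(value, nr, nc)
}
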