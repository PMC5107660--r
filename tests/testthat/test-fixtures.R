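test_that("micrograph generation is deterministic and truth-complete", {
  spec <- micrograph_spec(n_nuclei = 20, n_clumps = 1, clump_nuclei = 2,
                          n_debris = 2, seed = 42)
  a <- generate_micrograph(spec)
  b <- generate_micrograph(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 22)  # isolated + in-clump nuclei
  # empty spec: uniform background, empty truth
  e <- generate_micrograph(micrograph_spec(n_nuclei = 0, seed = 1))
  expect_true(all(e$image == 230))
  expect_equal(nrow(e$truth), 0)
  # an over-full canvas fails loudly
  expect_error(
    generate_micrograph(micrograph_spec(image_size = c(40, 40),
                                        n_nuclei = 200, seed = 1)),
    "too crowded|could not place"
  )
})

test_that("debris is detectable by neither rule, clumps trigger masks", {
  spec <- micrograph_spec(n_nuclei = 10, n_clumps = 2, clump_nuclei = 3,
                          n_debris = 3, seed = 11)
  fx <- generate_micrograph(spec)
  masks <- detect_masks(fx$image)
  expect_equal(masks$n_masks, 2)
  res <- analyze_image(fx$image)
  expect_equal(res$n_cells, nrow(fx$truth))  # debris adds nothing
})

test_that("detection recovers ground truth with high precision and recall", {
  matched <- function(truth, points, tol = 1.5) {
    hits <- 0
    for (i in seq_len(nrow(truth))) {
      d2 <- (points$row - truth$row[i])^2 + (points$col - truth$col[i])^2
      if (length(d2) > 0 && min(d2) <= tol^2) hits <- hits + 1
    }
    hits
  }
  for (seed in 1:3) {
    fx <- generate_micrograph(micrograph_spec(n_nuclei = 40, seed = seed))
    cents <- detect_nuclei(fx$image)
    tp <- matched(fx$truth, cents$points, tol = 1)  # within 1 px
    expect_gte(tp / nrow(fx$truth), 0.95)           # recall
    expect_gte(tp / cents$n_cells, 0.95)            # precision
  }
})

test_that("point patterns have the requested structure", {
  u <- generate_point_pattern(500, "uniform", seed = 1)
  expect_equal(nrow(u), 500)
  expect_true(all(u$x >= 0 & u$x <= 100 & u$y >= 0 & u$y <= 100))
  cl <- generate_point_pattern(500, "clustered", dispersion = 2,
                               n_clusters = 4, seed = 1)
  # clustered points have far smaller mean nearest-neighbor distance
  nn <- function(p) {
    d <- as.matrix(dist(cbind(p$x, p$y)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  expect_lt(nn(cl), 0.5 * nn(u))
  expect_identical(cl, generate_point_pattern(500, "clustered", dispersion = 2,
                                              n_clusters = 4, seed = 1))
  expect_error(generate_point_pattern(1, "uniform"), "n >= 2")
})

test_that("tightening clusters does not decrease CVHV", {
  # dispersion ladder at fixed n, paired by seed (same cluster centers and
  # deviates, scaled): CVHV medians ordered tight >= loose
  ladder <- c(1, 4, 16)
  vals <- sapply(ladder, function(disp) {
    sapply(1:20, function(s) {
      p <- generate_point_pattern(120, "clustered", dispersion = disp,
                                  n_clusters = 5, seed = 1000 + s)
      cvhv(voronoi_tessellate(p, bounds = c(0, 100, 0, 100),
                              polygons = FALSE))
    })
  })
  meds <- apply(vals, 2, median)
  expect_true(all(diff(meds) <= 0))
  # and the tighter member of each adjacent pair usually wins
  expect_gt(mean(vals[, 1] >= vals[, 2]), 0.7)
  expect_gt(mean(vals[, 2] >= vals[, 3]), 0.7)
})

test_that("uniform-pattern CVHV is stable across seeds", {
  vals <- sapply(1:50, function(s) {
    p <- generate_point_pattern(1000, "uniform", seed = s)
    cvhv(voronoi_tessellate(p, bounds = c(0, 100, 0, 100), polygons = FALSE))
  })
  expect_lt(sd(vals) / mean(vals), 0.2)
})

test_that("rendered slices round-trip through the detection pipeline", {
  # empty point set: blank image
  blank <- render_slice(data.frame(x = numeric(0), y = numeric(0)))
  expect_true(all(blank == 230))
  # one point at the slice center: single dark disc at the image center
  one <- render_slice(data.frame(x = -0.5, y = -0.5), scale = 8)
  expect_equal(dim(one), c(256, 256))
  dark <- which(one < 125, arr.ind = TRUE)
  expect_equal(mean(dark[, 1]), 128, tolerance = 0.01)
  expect_equal(mean(dark[, 2]), 128, tolerance = 0.01)
  # well-separated points: rendered-then-detected count equals point count
  set.seed(33)
  pts <- expand.grid(x = seq(-14, 14, by = 4), y = seq(-14, 14, by = 4))
  pts <- pts + matrix(runif(nrow(pts) * 2, -1, 1), ncol = 2)
  img <- render_slice(pts, scale = 8)
  cents <- detect_nuclei(img)
  expect_equal(cents$n_cells, nrow(pts))
  # detected pixel centroids map back to patch coordinates within 1 px
  mapping <- attr(img, "mapping")
  back_x <- mapping$bounds[1] + cents$points$col / mapping$scale
  back_y <- mapping$bounds[3] + cents$points$row / mapping$scale
  nearest <- vapply(seq_len(nrow(pts)), function(i) {
    which.min((back_x - pts$x[i])^2 + (back_y - pts$y[i])^2)
  }, integer(1))
  expect_equal(sort(nearest), seq_len(nrow(pts)))  # one detection per point
  err_px <- sqrt((back_x[nearest] - pts$x)^2 +
                   (back_y[nearest] - pts$y)^2) * mapping$scale
  expect_lt(max(err_px), 1)
})

test_that("coordinate-direct and rendered-image CVHV agree", {
  set.seed(44)
  pts <- expand.grid(x = seq(-13, 13, by = 3.8), y = seq(-13, 13, by = 3.8))
  pts <- pts + matrix(runif(nrow(pts) * 2, -1.2, 1.2), ncol = 2)
  direct <- analyze_slice_points(pts, bounds = c(-16.5, 15.5, -16.5, 15.5))
  img <- render_slice(pts, scale = 8)
  rendered <- analyze_image(img)
  expect_equal(rendered$n_cells, direct$n_cells)
  # pixel areas scale by scale^2, so CVHV scales by scale^4 x n-consistency
  expect_equal(rendered$cvhv / 8^4, direct$cvhv, tolerance = 0.1)
})
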