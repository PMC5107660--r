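test_that("grayscale conversion is luminance-based and idempotent", {
  white <- array(1, dim = c(4, 4, 3))
  expect_equal(to_grayscale(white), matrix(255, 4, 4))
  # equal channels pass through: mid-gray stays 128
  gray <- array(128 / 255, dim = c(3, 3, 3))
  expect_equal(to_grayscale(gray), matrix(128, 3, 3), tolerance = 1e-12)
  # already-grayscale 0-255 input is unchanged
  img <- matrix(c(0, 60, 125, 255), 2, 2)
  expect_identical(to_grayscale(img), img)
  expect_identical(to_grayscale(to_grayscale(img)), to_grayscale(img))
  expect_error(to_grayscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("mask detection keeps only dark components of at least min_size", {
  expect_equal(detect_masks(blank_image())$n_masks, 0)
  # exactly 500 dark pixels in one block -> one mask of 500 px
  img <- paint_block(blank_image(80, 80), 10, 10, 10, 50, 60)
  m <- detect_masks(img)
  expect_equal(m$n_masks, 1)
  expect_equal(m$components$size, 500)
  expect_equal(sum(m$mask), 500)
  # 13 x 23 = 299 px: one pixel under the floor -> no mask
  img2 <- paint_block(blank_image(80, 80), 10, 10, 13, 23, 60)
  expect_equal(detect_masks(img2)$n_masks, 0)
  # exactly 300 px passes
  img3 <- paint_block(blank_image(80, 80), 10, 10, 12, 25, 60)
  expect_equal(detect_masks(img3)$n_masks, 1)
  # threshold polarity: dark foreground means intensity < threshold
  img4 <- paint_block(blank_image(80, 80), 10, 10, 20, 20, 125)
  expect_equal(detect_masks(img4, threshold = 125)$n_masks, 0)
})

test_that("connectivity switch separates diagonal components", {
  img <- blank_image(20, 20)
  img[5, 5] <- 60
  img[6, 6] <- 60  # touches only diagonally
  c8 <- recell:::.cpp_label_components(img < 125, 8L)
  c4 <- recell:::.cpp_label_components(img < 125, 4L)
  expect_equal(max(c8), 1)
  expect_equal(max(c4), 2)
})

test_that("nucleus detection applies the dual-threshold, size-capped rules", {
  # five isolated 2 x 5 = 10 px blobs at known centers
  img <- blank_image(100, 100)
  at <- list(c(10, 10), c(10, 60), c(50, 30), c(80, 80), c(90, 12))
  for (p in at) img <- paint_block(img, p[1], p[2], 2, 5, 60)
  cents <- detect_nuclei(img)
  expect_equal(cents$n_cells, 5)
  truth_row <- sapply(at, function(p) p[1] + 0.5)
  truth_col <- sapply(at, function(p) p[2] + 2)
  ord <- order(cents$points$row, cents$points$col)
  tord <- order(truth_row, truth_col)
  expect_equal(cents$points$row[ord], truth_row[tord])
  expect_equal(cents$points$col[ord], truth_col[tord])
  # a 25-px blob exceeds the 20-px ceiling and is ignored
  img2 <- paint_block(blank_image(), 10, 10, 5, 5, 60)
  expect_equal(detect_nuclei(img2)$n_cells, 0)
  # blank image: empty centroid set
  expect_equal(detect_nuclei(blank_image())$n_cells, 0)
})

test_that("in-mask nuclei are found at the stricter threshold only", {
  # clump body at 110 (mask-forming, not nucleus-dark) with two 60-intensity
  # sub-blobs inside
  img <- paint_block(blank_image(80, 80), 20, 20, 20, 20, 110)
  img <- paint_block(img, 24, 24, 2, 5, 60)
  img <- paint_block(img, 32, 28, 2, 5, 60)
  masks <- detect_masks(img)
  expect_equal(masks$n_masks, 1)
  cents <- detect_nuclei(img, masks)
  expect_equal(cents$n_cells, 2)
  expect_true(all(cents$points$region == "inside"))
  # without the mask pass (threshold_inside = 0), nothing inside is found
  none <- detect_nuclei(img, masks, threshold_inside = 0)
  expect_equal(none$n_cells, 0)
})

test_that("centroid edits append, remove-nearest, and log", {
  img <- blank_image(100, 100)
  for (p in list(c(10, 10), c(10, 60), c(50, 30), c(80, 80), c(90, 12))) {
    img <- paint_block(img, p[1], p[2], 2, 5, 60)
  }
  cents <- detect_nuclei(img)
  e1 <- edit_centroids(cents, add = data.frame(row = c(30, 40), col = c(5, 5)))
  expect_equal(e1$n_cells, 7)
  e2 <- edit_centroids(e1, remove = data.frame(row = 10.4, col = 12.2),
                       tolerance = 2)
  expect_equal(e2$n_cells, 6)
  expect_equal(nrow(e2$edit_log), 3)
  expect_equal(e2$edit_log$action, c("add", "add", "remove"))
  # removal with no centroid nearby names the offending point
  expect_error(
    edit_centroids(cents, remove = data.frame(row = 99, col = 99)),
    "no centroid within"
  )
  expect_error(
    edit_centroids(cents, add = data.frame(row = 500, col = 5)),
    "within the image"
  )
})

test_that("the composed pipeline counts cells and measures clustering", {
  fx <- generate_micrograph(micrograph_spec(n_nuclei = 40, seed = 99))
  res <- analyze_image(fx$image)
  expect_equal(res$n_cells, 40)
  # CVHV within 5% of the value computed from ground-truth positions
  truth_tess <- voronoi_tessellate(
    data.frame(x = fx$truth$col, y = fx$truth$row),
    bounds = c(0.5, 256.5, 0.5, 256.5), polygons = FALSE
  )
  expect_equal(res$cvhv, cvhv(truth_tess), tolerance = 0.05)
  expect_error(analyze_image(blank_image()), "empty point set|no nuclei")
})

test_that("image round-trips through PNG preserve the analysis", {
  fx <- generate_micrograph(micrograph_spec(n_nuclei = 15, seed = 5))
  path <- withr::local_tempfile(fileext = ".png")
  write_micrograph(fx$image, path)
  back <- read_micrograph(path)
  expect_equal(back, fx$image, ignore_attr = TRUE)
  expect_equal(analyze_image(path)$n_cells, 15)
})
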