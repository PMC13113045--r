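test_that("segmentation finds the right components and respects min_area", {
  img <- matrix(10, 80, 80)
  img[20:30, 10:60] <- 150                  # bright rod
  set.seed(1)
  img <- img + matrix(stats::rnorm(6400, 0, 2), 80, 80)
  rois <- segment(img, pixel_size = 1, min_area = 50)
  expect_equal(max(rois$labels), 1L)
  # blank image: zero components
  expect_equal(max(segment(matrix(10, 40, 40) +
                             matrix(stats::rnorm(1600, 0, 0.1), 40, 40),
                           1, 50)$labels), 0L)
  # two non-touching cells recovered with areas within 5 %
  g1 <- gen_cell_image(cell_image_truth(40, 12), pixel_size = 0.5, seed = 2)
  g2 <- gen_cell_image(cell_image_truth(30, 30), pixel_size = 0.5, seed = 3)
  n1 <- nrow(g1$image); n2 <- nrow(g2$image)
  canvas <- matrix(10, n1, n1 + n2 + 10)
  canvas[1:n1, 1:n1] <- g1$image
  canvas[1:n2, n1 + 11:(10 + n2)] <- g2$image
  rois2 <- segment(canvas, pixel_size = 0.5, min_area = 50)
  expect_equal(max(rois2$labels), 2L)
  areas <- vapply(1:2, function(l) sum(roi_mask(rois2, l)) * 0.25,
                  numeric(1))
  truth_areas <- c(g1$truth$descriptor_truth$area,
                   g2$truth$descriptor_truth$area)
  expect_equal(sort(areas), sort(truth_areas), tolerance = 0.05)
})

test_that("descriptors are exact on analytic shapes", {
  d <- descriptors(disk_mask(50), pixel_size = 0.5)
  expect_equal(d$circularity, 1, tolerance = 0.03)
  expect_equal(d$feret, 50, tolerance = 0.02)      # 2r = 50 um
  expect_equal(d$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(d$area, pi * 25^2, tolerance = 0.01)
  sq <- descriptors(square_mask(100), pixel_size = 0.5)
  expect_equal(sq$circularity, pi / 4, tolerance = 0.03)
  expect_error(descriptors(matrix(TRUE, 2, 2)), "16 pixels")
})

test_that("a 1-pixel-wide region falls back to bounding geometry with a flag", {
  line <- matrix(FALSE, 10, 40); line[5, 3:38] <- TRUE
  d <- descriptors(line, pixel_size = 1)
  expect_true(d$degenerate)
  expect_equal(d$aspect_ratio, 36, tolerance = 0.01)
})

test_that("circularity is invariant under rotation and uniform scaling", {
  base <- cell_image_truth(80, 25)
  circs <- vapply(c(0, 23, 45, 77), function(ang) {
    m <- gen_cell_image(cell_image_truth(80, 25, orientation = ang),
                        pixel_size = 0.4, noise_sd = 0)$mask
    descriptors(m, 0.4)$circularity
  }, numeric(1))
  expect_lt(diff(range(circs)) / mean(circs), 0.03)
  # uniform scaling: same shape at double resolution
  c1 <- descriptors(disk_mask(30), 1)$circularity
  c2 <- descriptors(disk_mask(60), 0.5)$circularity
  expect_equal(c1, c2, tolerance = 0.03)
})

test_that("feret of a disk converges to its diameter with resolution", {
  ratios <- vapply(c(20, 40, 80), function(r)
    mask_feret(disk_mask(r), 1) / (2 * r), numeric(1))
  expect_true(all(abs(ratios - 1) < 0.01))
  expect_true(abs(ratios[3] - 1) <= abs(ratios[1] - 1) + 0.005)
})

test_that("box-counting dimension: ~1 for smooth outlines, ~1.26 for the Koch curve", {
  expect_equal(fractal_dimension(disk_mask(60)), 1, tolerance = 0.12)
  expect_equal(fractal_dimension(koch_curve_mask(6), outline = FALSE),
               log(4) / log(3), tolerance = 0.08 / 1.26)
})

test_that("striation FFT recovers the generated period and is rotation-invariant", {
  g <- gen_cell_image(cell_image_truth(100, 20, striation_period = 2.0),
                      pixel_size = 0.2, seed = 5)
  r <- striation_fft(g$image, g$mask, 0.2)
  expect_true(r$is_striated)
  expect_equal(r$dominant_period, 2.0, tolerance = 0.05)
  g37 <- gen_cell_image(cell_image_truth(100, 20, orientation = 37,
                                         striation_period = 2.0),
                        pixel_size = 0.2, seed = 5)
  r37 <- striation_fft(g37$image, g37$mask, 0.2)
  expect_true(r37$is_striated)
  expect_equal(r37$dominant_period, r$dominant_period, tolerance = 0.05)
  # unstriated rod is negative
  gu <- gen_cell_image(cell_image_truth(100, 20), pixel_size = 0.2,
                       seed = 6)
  expect_false(striation_fft(gu$image, gu$mask, 0.2)$is_striated)
  # region shorter than 4 band periods is unmeasurable
  gs <- gen_cell_image(cell_image_truth(10, 8), pixel_size = 0.2, seed = 7)
  rs <- striation_fft(gs$image, gs$mask, 0.2)
  expect_false(rs$measurable)
})

test_that("group comparison flags separated parameters and not identical ones", {
  set.seed(4)
  rods <- dplyr::bind_rows(lapply(1:8, function(i)
    descriptors(gen_cell_image(
      cell_image_truth(stats::runif(1, 80, 120), stats::runif(1, 15, 25),
                       orientation = stats::runif(1, 0, 180)),
      pixel_size = 0.5, seed = i)$mask, 0.5)))
  rounds <- dplyr::bind_rows(lapply(1:9, function(i)
    descriptors(gen_cell_image(
      cell_image_truth(stats::runif(1, 45, 60), stats::runif(1, 40, 45),
                       orientation = stats::runif(1, 0, 180)),
      pixel_size = 0.5, seed = 100 + i)$mask, 0.5)))
  cmp <- compare_groups(rods, rounds, alpha = 0.01)
  expect_true(cmp$significant[cmp$parameter == "aspect_ratio"])
  # identical groups: p = 1 everywhere, no flags
  same <- compare_groups(rods, rods, alpha = 0.05)
  expect_true(all(same$p_value == 1))
  expect_false(any(same$significant))
  expect_error(compare_groups(rods[1:2, ], rounds), "group a")
  # the reported p agrees with the exact enumeration oracle (normal
  # approximation at n = 8 vs 9) and the flag matches the oracle's
  o <- mw_oracle(rods$aspect_ratio, rounds$aspect_ratio)
  p_pkg <- cmp$p_value[cmp$parameter == "aspect_ratio"]
  expect_lt(abs(p_pkg - o$p), 0.02)
  expect_equal(p_pkg < 0.01, o$p < 0.01)
})
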