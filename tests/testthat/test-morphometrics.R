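test_that("segmentation counts objects and applies the area filter", {
  img <- matrix(0, 128, 128)
  rr <- row(img); cc <- col(img)
  img[(rr - 30)^2 + (cc - 30)^2 <= 15^2] <- 1
  img[(rr - 90)^2 + (cc - 90)^2 <= 4^2] <- 1
  expect_equal(segment_threshold(img, "fixed", threshold = 0.5)$n_objects, 2)
  expect_equal(segment_threshold(img, "fixed", threshold = 0.5,
                                 min_area_px = 100)$n_objects, 1)
  expect_equal(segment_threshold(matrix(0, 64, 64), "fixed",
                                 threshold = 0.5)$n_objects, 0)
  # otsu separates a bimodal image without a manual threshold
  set.seed(1)
  noisy <- img * 0.7 + matrix(rnorm(128 * 128, 0.1, 0.03), 128, 128)
  expect_equal(segment_threshold(noisy, "otsu", min_area_px = 20)$n_objects, 2)
})

test_that("labeling is 8-connected", {
  img <- matrix(0, 16, 16)
  img[cbind(4:8, 4:8)] <- 1   # diagonal chain: one object under 8-connectivity
  expect_equal(segment_threshold(img, "fixed", threshold = 0.5)$n_objects, 1)
})

test_that("disk descriptors approach the analytic circle limits", {
  m <- segment_threshold(raster_disk(50), "fixed", threshold = 0.5)
  d <- shape_descriptors(m)
  expect_gt(d$circularity, 0.95); expect_lt(d$circularity, 1.05)
  expect_gte(d$aspect_ratio, 1); expect_lt(d$aspect_ratio, 1.05)
  expect_gte(d$solidity, 0.98)
  # pixel size propagates to physical units
  m2 <- m; m2$pixel_size_um <- 0.25
  d2 <- shape_descriptors(m2)
  expect_equal(d2$area_um2, d$area_um2 / 16)
  expect_equal(d2$perimeter_um, d$perimeter_um / 4)
})

test_that("disk circularity converges monotonically to 1 with radius", {
  circ <- vapply(c(10, 30, 100), function(r) {
    shape_descriptors(segment_threshold(raster_disk(r), "fixed",
                                        threshold = 0.5))$circularity
  }, numeric(1))
  expect_true(all(diff(circ) > 0))
  expect_lt(abs(circ[3] - 1), 0.01)
})

test_that("moment-matched ellipse recovers the axis ratio", {
  d <- shape_descriptors(segment_threshold(raster_ellipse(40, 20), "fixed",
                                           threshold = 0.5))
  expect_equal(d$aspect_ratio, 2.0, tolerance = 0.025)
})

test_that("a plus-shaped object has low solidity", {
  img <- matrix(0, 128, 128)
  img[54:74, 20:108] <- 1
  img[20:108, 54:74] <- 1
  d <- shape_descriptors(segment_threshold(img, "fixed", threshold = 0.5))
  expect_lt(d$solidity, 0.9)
  # brute-force check of the hull area: the plus spans a 89 x 89 bounding
  # octagon; its pixel-set hull area must exceed the plus area
  expect_gt(d$area_um2 / d$solidity, d$area_um2)
})

test_that("descriptors are invariant to rotation by 90 degrees and to gain", {
  img <- raster_ellipse(35, 18)
  d1 <- shape_descriptors(segment_threshold(img, "fixed", threshold = 0.5))
  d2 <- shape_descriptors(segment_threshold(t(img)[ncol(img):1, ],
                                            "fixed", threshold = 0.5))
  for (col in c("area_um2", "perimeter_um", "aspect_ratio", "circularity",
                "solidity"))
    expect_lt(abs(d1[[col]] - d2[[col]]) / d1[[col]], 0.02)
  d3 <- shape_descriptors(segment_threshold(img * 7, "fixed",
                                            threshold = 3.5))
  expect_equal(d3$aspect_ratio, d1$aspect_ratio)
})

test_that("degenerate objects are flagged, not fatal", {
  img <- matrix(0, 32, 32)
  img[16, 5:25] <- 1   # one-pixel line
  d <- shape_descriptors(segment_threshold(img, "fixed", threshold = 0.5))
  expect_equal(d$flags, "degenerate")
  expect_true(is.na(d$aspect_ratio))
})

test_that("holes are filled before measuring the external margin", {
  full <- raster_disk(30)
  holed <- full
  ctr <- (nrow(full) + 1) / 2
  holed[(row(full) - ctr)^2 + (col(full) - ctr)^2 <= 10^2] <- 0
  d_full <- shape_descriptors(segment_threshold(full, "fixed",
                                                threshold = 0.5))
  d_holed <- shape_descriptors(segment_threshold(holed, "fixed",
                                                 threshold = 0.5))
  # external-margin descriptors are identical once the hole is filled
  expect_equal(d_holed$circularity, d_full$circularity)
  expect_equal(d_holed$solidity, d_full$solidity)
  expect_equal(d_holed$perimeter_um, d_full$perimeter_um)
})

test_that("tumor area ratio is the covered body fraction", {
  body <- matrix(TRUE, 10, 10)
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_equal(tumor_area_ratio(half, body), 0.5)
  expect_equal(tumor_area_ratio(matrix(FALSE, 10, 10), body), 0)
  expect_equal(tumor_area_ratio(body, half), 1)
  expect_error(tumor_area_ratio(half, matrix(FALSE, 10, 10)), "empty")
  expect_error(tumor_area_ratio(matrix(TRUE, 3, 3), body), "congruent")
})

test_that("synthetic cell populations close the loop with the generator", {
  sim <- simulate_cell_image(cell_population_spec(1, aspect_ratio_mean = 2,
                                                  aspect_ratio_sd = 0,
                                                  boundary_roughness = 0,
                                                  image_size_px = 160,
                                                  seed = 5))
  d <- shape_descriptors(segment_threshold(sim$image, "otsu",
                                           min_area_px = 30))
  expect_equal(d$aspect_ratio, 2.0, tolerance = 0.05)

  # rough margins depress solidity
  smooth <- simulate_cell_image(cell_population_spec(6, boundary_roughness = 0,
                                                     image_size_px = 320,
                                                     seed = 6))
  rough <- simulate_cell_image(cell_population_spec(6, boundary_roughness = 0.5,
                                                    image_size_px = 320,
                                                    seed = 6))
  sol <- function(x) mean(shape_descriptors(
    segment_threshold(x$image, "otsu", min_area_px = 30))$solidity)
  expect_lt(sol(rough), sol(smooth))
})
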