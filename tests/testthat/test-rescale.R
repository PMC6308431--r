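# The scaling algorithm: equalization, binarization, small-circle
# localization, watershed fallback, bicubic expansion.

test_that("histogram equalization follows the CDF mapping", {
  expect_true(all(equalize_histogram(matrix(42, 20, 20)) == 42))

  # two-value image 50/50: maps to {0, 255} up to quantization
  two <- matrix(c(0, 255), 16, 16)
  eq <- equalize_histogram(two)
  expect_setequal(unique(as.vector(eq)), c(0, 255))

  # a linear ramp already has a uniform histogram: mapping ~ identity
  ramp <- matrix(rep(0:255, each = 4), 32, 32)
  eqr <- equalize_histogram(ramp)
  expect_lt(max(abs(eqr - ramp)), 3)
})

test_that("binarization isolates a bright ring and normalizes polarity", {
  img <- matrix(30, 200, 200) + matrix(rnorm(200 * 200, 0, 2), 200, 200)
  ring <- draw_ring(200, 200, 100, 100, 40, thickness = 6)
  img[ring] <- 220
  mask <- contrast_magnify_binarize(img)
  expect_gt(mean(mask[ring]), 0.9)
  expect_lt(mean(mask[!ring]), 0.02)

  expect_false(any(contrast_magnify_binarize(matrix(7, 50, 50))))

  # inverted image: foreground is still the (dark) ring minority class
  mask_inv <- contrast_magnify_binarize(255 - img)
  expect_gt(mean(mask_inv[ring]), 0.9)
  expect_lt(mean(mask_inv[!ring]), 0.02)
})

test_that("variable_range_hough finds embryos in both smartphone regimes", {
  for (cfg in list(list(r = 15, regime = "smartphone_d2"),
                   list(r = 60, regime = "smartphone_d1"))) {
    rb <- render_blastocyst(synthetic_spec(cfg$regime, radius = cfg$r,
                                           seed = 23))
    gray <- to_grayscale(rb$image)
    det <- variable_range_hough(contrast_magnify_binarize(gray))
    expect_false(is.null(det))
    expect_lte(abs(det$radius - cfg$r), 3)
    expect_lte(abs(det$center_row - rb$truth$center_row), 3)
    expect_lte(abs(det$center_col - rb$truth$center_col), 3)
  }
  expect_null(variable_range_hough(matrix(FALSE, 100, 100)))
})

test_that("watershed fallback prefers the circular blob", {
  mask <- matrix(FALSE, 200, 260)
  mask[disk_mask_for_test(200, 260, 100, 70, 30)] <- TRUE        # circular
  mask[80:120, 140:250] <- TRUE                                  # elongated
  ws <- watershed_fallback(mask)
  expect_false(is.null(ws))
  expect_lte(abs(ws$center_row - 100), 5)
  expect_lte(abs(ws$center_col - 70), 5)
  expect_lte(abs(ws$radius - 30), 4)

  expect_null(watershed_fallback(matrix(FALSE, 50, 50)))

  disk_only <- matrix(FALSE, 120, 120)
  disk_only[disk_mask_for_test(120, 120, 60, 60, 25)] <- TRUE
  wd <- watershed_fallback(disk_only)
  expect_gte(wd$circularity, 0.9)
})

test_that("bicubic expansion is exact for polynomial surfaces", {
  const <- bicubic_expand(matrix(9, 30, 30), c(1, 30, 1, 30), 3)
  expect_true(all(abs(const - 9) < 1e-9))

  x <- seq_len(40); y <- seq_len(40)
  f <- outer(x, y, function(a, b)
    0.001 * a^3 - 0.004 * b^3 + 0.03 * a * b^2 - 0.2 * a * b + a + 2 * b + 5)
  out <- bicubic_expand(f, c(1, 40, 1, 40), 2.5, clip = FALSE)
  xo <- (seq_len(nrow(out)) - 0.5) / 2.5 + 0.5
  yo <- (seq_len(ncol(out)) - 0.5) / 2.5 + 0.5
  kr <- xo >= 3 & xo <= 38; kc <- yo >= 3 & yo <= 38  # interior (no clamping)
  truth <- outer(xo[kr], yo[kc], function(a, b)
    0.001 * a^3 - 0.004 * b^3 + 0.03 * a * b^2 - 0.2 * a * b + a + 2 * b + 5)
  expect_lt(max(abs(out[kr, kc] - truth)), 1e-6)

  # geometry: scale 2 on a 100x100 crop gives 200x200
  big <- matrix(runif(150 * 150), 150, 150)
  out2 <- bicubic_expand(big, c(26, 125, 26, 125), 2)
  expect_equal(dim(out2), c(200, 200))

  expect_error(bicubic_expand(big, c(1, 4, 1, 4), 2), "egenerate crop")
})

test_that("rescale_image lifts small embryos into the detectable range", {
  for (r in c(15, 60)) {
    regime <- if (r < 30) "smartphone_d2" else "smartphone_d1"
    rb <- render_blastocyst(synthetic_spec(regime, radius = r, seed = 29))
    res <- rescale_image(rb$image)
    expect_equal(res$found_by, "hough_variable_range")
    expect_equal(dim(res$output$pixels), c(480, 640))
    det <- two_stage_detect(binarize(gradient_magnitude(res$output)))
    expect_false(is.null(det))
    expect_gte(det$radius, 100)
    expect_lte(det$radius, 200)
  }
})

test_that("rescale_image reports not_found on pure noise", {
  set.seed(31)
  for (trial in 1:3) {
    noise <- new_raw_image(matrix(runif(480 * 640) * 255, 480, 640))
    res <- rescale_image(noise)
    expect_equal(res$found_by, "not_found")
    expect_null(res$output)
  }
})

test_that("the expansion factor is capped", {
  # a tiny found circle may not be upscaled by more than 20x
  rb <- render_blastocyst(synthetic_spec("smartphone_d2", radius = 10,
                                         seed = 33))
  res <- rescale_image(rb$image, target_radius = 300)
  if (!identical(res$found_by, "not_found"))
    expect_lte(res$scale_factor, 20)
})
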