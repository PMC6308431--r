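# Gradient, thresholding, circular Hough detection and region isolation.

test_that("gradient magnitude matches direct Sobel evaluation on toys", {
  expect_true(all(gradient_magnitude(matrix(50, 20, 20)) == 0))

  # vertical step edge: maxima on the two columns flanking the step,
  # zero far away
  step <- cbind(matrix(0, 20, 10), matrix(255, 20, 10))
  g <- gradient_magnitude(step)
  expect_true(all(g[, c(10, 11)] == 4 * 255))  # Sobel row sums to 4 per side
  expect_true(all(g[, c(1:8, 13:20)] == 0))

  # single bright pixel: nonzero only in its 3x3 Sobel footprint
  spot <- matrix(0, 9, 9); spot[5, 5] <- 100
  gs <- gradient_magnitude(spot)
  nz <- which(gs > 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 5) <= 1 & abs(nz[, 2] - 5) <= 1))
  # hand-computed corner of the footprint: gx = gy = 100 -> 100*sqrt(2)
  expect_equal(gs[4, 4], 100 * sqrt(2))
})

test_that("binarize applies the inclusive 128 threshold after rescale", {
  expect_false(any(binarize(matrix(0, 5, 5))))
  toy <- matrix(c(0, 127, 128, 255, 64, 128, 200, 10, 128), 3, 3)
  expect_identical(binarize(toy, rescale = FALSE), toy >= 128)
  # min-max rescale makes the fixed cut exposure-invariant
  expect_identical(binarize(toy / 10, threshold = 128),
                   binarize(toy, threshold = 128))
})

test_that("hough_circles recovers a clean rasterized ring", {
  ring <- draw_ring(480, 640, 240, 320, 120)
  cand <- hough_circles(ring, 100, 150, r_step = 1)
  expect_gt(nrow(cand), 0)
  expect_lte(abs(cand$radius[1] - 120), 3)
  expect_lte(abs(cand$center_row[1] - 240), 3)
  expect_lte(abs(cand$center_col[1] - 320), 3)

  expect_equal(nrow(hough_circles(matrix(FALSE, 100, 100), 10, 30)), 0)
  expect_error(hough_circles(ring, 150, 100), "r_min")
})

test_that("a complete ring outvotes a half-erased ring", {
  img <- draw_ring(480, 640, 200, 200, 110)
  half <- draw_ring(480, 640, 250, 450, 130)
  half[, 450:640] <- FALSE  # erase half the second ring
  both <- img | half
  cand <- hough_circles(both, 100, 150, r_step = 1)
  r110 <- cand[abs(cand$radius - 110) <= 1, ][1, ]
  r130 <- cand[abs(cand$radius - 130) <= 1, ][1, ]
  expect_gt(r110$strength, r130$strength)
})

test_that("two_stage_detect finds 100-200 px embryos and nothing smaller", {
  s <- segment_synthetic(165, seed = 42)
  expect_false(is.null(s$detection))
  expect_equal(s$detection$stage, "stage2_150_200")
  expect_lte(abs(s$detection$radius - 165), 5)

  # smartphone-size embryo: both windows miss
  small <- segment_synthetic(60, seed = 42, regime = "smartphone_d1")
  expect_null(small$detection)

  expect_null(two_stage_detect(matrix(FALSE, 480, 640)))
})

test_that("sub-100-px embryos are never detected by the two-stage search", {
  for (seed in 1:4) {
    s <- segment_synthetic(sample(30:90, 1), seed = seed,
                           regime = "smartphone_d1")
    expect_null(s$detection)
  }
})

test_that("detection is translation-equivariant", {
  base <- c(220, 300)
  s0 <- segment_synthetic(130, seed = 3)
  # re-render at a controlled center, then at a shifted center
  r1 <- render_blastocyst(synthetic_spec("microscope", radius = 130,
                                         center = base, seed = 3))
  r2 <- render_blastocyst(synthetic_spec("microscope", radius = 130,
                                         center = base + c(25, -40), seed = 3))
  d1 <- two_stage_detect(binarize(gradient_magnitude(standardize(r1$image))))
  d2 <- two_stage_detect(binarize(gradient_magnitude(standardize(r2$image))))
  expect_lte(abs((d2$center_row - d1$center_row) - 25), 2)
  expect_lte(abs((d2$center_col - d1$center_col) - (-40)), 2)
})

test_that("isolate_regions applies the +5/-40 offsets and partitions ER", {
  s <- segment_synthetic(150, seed = 9)
  seg <- isolate_regions(s$std, s$detection)
  expect_equal(seg$er_radius, s$detection$radius + 5)
  expect_equal(seg$rr_radius, s$detection$radius - 40)

  # partition: er = rr (disjoint union) te
  expect_true(all(seg$te_mask == (seg$er_mask & !seg$rr_mask)))
  expect_true(all(seg$rr_mask | !seg$te_mask | !seg$rr_mask))
  expect_false(any(seg$rr_mask & seg$te_mask))
  expect_equal(sum(seg$te_mask), sum(seg$er_mask) - sum(seg$rr_mask))

  # masked intensities: original inside, zero outside
  expect_true(all(seg$er_image[!seg$er_mask] == 0))
  expect_identical(seg$er_image[seg$er_mask], s$std$pixels[seg$er_mask])

  # er area equals brute-force integer disk-point count
  circ <- list(center_row = 240, center_col = 320, radius = 100,
               strength = 1, stage = "stage1_100_150")
  seg2 <- isolate_regions(matrix(100, 480, 640), circ)
  count <- 0
  for (r in 135:345) for (c in 215:425)
    if ((r - 240)^2 + (c - 320)^2 <= 105^2) count <- count + 1
  expect_equal(sum(seg2$er_mask), count)

  small <- list(center_row = 240, center_col = 320, radius = 40,
                strength = 1, stage = "stage1_100_150")
  expect_error(isolate_regions(matrix(0, 480, 640), small), "egenerate")
})

test_that("status classification follows the IoU bands against truth", {
  s <- segment_synthetic(150, seed = 5)
  truth <- s$rendered$truth
  seg <- isolate_regions(s$std, s$detection, truth = truth)
  expect_equal(seg$status, "full")

  # displace the detection so the disks overlap at IoU ~ 0.5: for equal
  # disks radius R, center distance 0.81 R gives lens IoU close to 0.5
  disp <- s$detection
  disp$center_col <- disp$center_col + round(0.81 * disp$radius)
  seg_p <- isolate_regions(s$std, disp, truth = truth)
  expect_equal(seg_p$status, "partial")

  far <- s$detection
  far$center_col <- 50; far$center_row <- 50
  # small far-away disk: IoU with the truth stays well below 0.3
  far$radius <- 42  # must stay > 40 for isolation
  seg_n <- isolate_regions(s$std, far, truth = truth)
  expect_equal(seg_n$status, "none")

  expect_equal(classify_status(structure(list(circle = NULL),
                                         class = "segmentation_result")),
               "none")
})
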