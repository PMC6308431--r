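# Synthetic blastocyst rendering and feature-dataset generation.

test_that("rendering is deterministic and sized for the canonical frame", {
  sp <- synthetic_spec("microscope", radius = 150, grade = 2, seed = 44)
  r1 <- render_blastocyst(sp)
  r2 <- render_blastocyst(sp)
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_equal(dim(r1$image$pixels), c(480, 640))
  expect_equal(r1$truth$radius, 150)
  # true region masks at the +5/-40 offsets
  expect_true(all(r1$truth$te_mask == (r1$truth$er_mask & !r1$truth$rr_mask)))

  expect_error(render_blastocyst(synthetic_spec("microscope", radius = 400)),
               "geometry")
})

test_that("occupancy measurements follow the closed forms", {
  occ <- measure_occupancy(list(radius = 162))
  expect_equal(occ$area_fraction, pi * 162^2 / (480 * 640))
  expect_lt(abs(occ$area_fraction - 0.268), 0.002)

  expect_equal(measure_occupancy(list(radius = 64))$interception_fraction,
               0.20)
  expect_equal(measure_occupancy(list(radius = 0))$area_fraction, 0)
  expect_error(measure_occupancy(list()), "circle")
})

test_that("regime defaults land in the calibrated occupancy bands", {
  # microscope: mean area fraction across draws near the 27% calibration
  fr <- vapply(1:30, function(i) {
    rb <- render_blastocyst(synthetic_spec("microscope", seed = 500 + i,
                                           noise_sd = 0))
    measure_occupancy(rb$truth)$area_fraction
  }, numeric(1))
  expect_gte(mean(fr), 0.20)
  expect_lte(mean(fr), 0.35)

  # smartphone_d2: every draw within the sub-percent band
  fr2 <- vapply(1:10, function(i) {
    rb <- render_blastocyst(synthetic_spec("smartphone_d2", seed = 600 + i,
                                           noise_sd = 0))
    measure_occupancy(rb$truth)$area_fraction
  }, numeric(1))
  expect_true(all(fr2 >= 0.001 & fr2 <= 0.005))
})

test_that("the detectors recover rendered ground truth per regime", {
  # microscope regime -> two-stage detector
  ok <- 0
  for (i in 1:10) {
    s <- segment_synthetic(sample(105:195, 1), seed = 700 + i)
    if (!is.null(s$detection) &&
        abs(s$detection$radius - s$rendered$truth$radius) <= 5)
      ok <- ok + 1
  }
  expect_gte(ok, 9)

  # smartphone regime -> scaling algorithm
  ok2 <- 0
  for (i in 1:5) {
    rb <- render_blastocyst(synthetic_spec("smartphone_d1", seed = 800 + i))
    res <- rescale_image(rb$image)
    if (!identical(res$found_by, "not_found") &&
        abs(res$small_circle$radius - rb$truth$radius) <= 5)
      ok2 <- ok2 + 1
  }
  expect_gte(ok2, 4)
})

test_that("feature datasets separate at high class distance, not at zero", {
  ds <- generate_feature_dataset(50, separation = 6, seed = 55)
  expect_equal(dim(ds$features), c(150, 24))
  # class-mean distances match the requested separation
  m1 <- colMeans(ds$features[ds$labels == 1, ])
  m2 <- colMeans(ds$features[ds$labels == 2, ])
  expect_lt(abs(sqrt(sum((m1 - m2)^2)) - 6), 0.8)

  spl <- split_dataset(ds$features, ds$labels, seed = 55)
  fx <- make_test_ensemble(seed = 55, n_per_class = 50)
  pred <- apply(fx$split$test$x, 1, function(r)
    ensemble_predict(fx$models, r)$final_grade)
  expect_gte(mean(pred == fx$split$test$y), 0.95)
  arch <- architecture(n_hidden = c(10, 8, 8), train_fn = "rprop")

  ds0 <- generate_feature_dataset(50, separation = 0, seed = 56)
  spl0 <- split_dataset(ds0$features, ds0$labels, seed = 56)
  ann0 <- train_ann(spl0$train, spl0$validation, arch, seed = 56,
                    max_epochs = 60)
  expect_lt(ann_accuracy(ann0, spl0$test), 0.67)
})

test_that("rendered grade classes are separable by the ensemble", {
  cfg <- default_config()
  segs <- list(); grades <- integer()
  for (g in 1:3) for (i in 1:20) {
    rb <- render_blastocyst(synthetic_spec("microscope", grade = g,
                                           seed = 900 + g * 40 + i))
    std <- standardize(rb$image)
    seg <- blastograde:::segment_standardized(std, cfg, truth = rb$truth)
    if (identical(seg$status, "none")) next
    segs[[length(segs) + 1]] <- seg
    grades <- c(grades, g)
  }
  expect_gte(length(grades), 50)
  ft <- as.matrix(feature_table(segs))
  spl <- split_dataset(ft, grades, seed = 5)
  archs <- list(
    architecture(n_hidden = c(16, 8, 8), train_fn = "rprop"),
    architecture(n_hidden = c(10, 10, 8), tf_hidden = rep("tanh_sigmoid", 3),
                 train_fn = "rprop", n_hidden_layers = 2),
    architecture(n_hidden = c(24, 8, 8),
                 train_fn = "gradient_descent_momentum"))
  models <- train_ensemble(spl, archs, seed = 7)
  pred <- apply(spl$test$x, 1, function(r)
    ensemble_predict(models, r)$final_grade)
  expect_gt(mean(pred == spl$test$y), 0.80)
})

test_that("fixture writer emits PNGs and a consistent manifest", {
  dir <- file.path(tempdir(), "synthfix")
  specs <- list(synthetic_spec("microscope", radius = 150, seed = 1),
                synthetic_spec("smartphone_d1", radius = 60, seed = 2))
  man <- write_synthetic_fixtures(dir, specs)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- png::readPNG(man$path[1])
  expect_equal(dim(back), c(480, 640))
})
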