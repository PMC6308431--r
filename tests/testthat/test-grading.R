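# Dataset splitting, backpropagation training, prediction, ensembles.

test_that("split_dataset yields stratified 70/15/15 partitions", {
  ds <- generate_feature_dataset(34, seed = 1)  # N = 102
  ds$features <- ds$features[1:100, ]; ds$labels <- ds$labels[1:100]
  spl <- split_dataset(ds$features, ds$labels, seed = 1)
  expect_equal(length(spl$train$y), 70)
  expect_equal(length(spl$validation$y), 15)
  expect_equal(length(spl$test$y), 15)
  expect_setequal(c(spl$train$idx, spl$validation$idx, spl$test$idx), 1:100)

  spl2 <- split_dataset(ds$features, ds$labels, seed = 1)
  expect_identical(spl, spl2)  # deterministic per seed

  # N = 20 balanced: every class present in every split
  small <- generate_feature_dataset(7, seed = 2)
  keep <- c(1:7, 8:14, 15:20)
  spl3 <- split_dataset(small$features[keep, ], small$labels[keep], seed = 3)
  for (part in spl3) expect_setequal(unique(part$y), 1:3)

  expect_error(split_dataset(ds$features[ds$labels != 2, ],
                             ds$labels[ds$labels != 2], seed = 1),
               "classes")
})

test_that("training reaches high accuracy on separable classes", {
  fx <- make_test_ensemble(seed = 5)
  acc <- vapply(fx$models, ann_accuracy, numeric(1), split = fx$split$test)
  expect_true(all(acc >= 0.95))
})

test_that("training is deterministic and a zero budget returns init only", {
  ds <- generate_feature_dataset(20, seed = 6)
  spl <- split_dataset(ds$features, ds$labels, seed = 6)
  arch <- architecture(n_hidden = c(6, 8, 8), train_fn = "rprop")
  a1 <- train_ann(spl$train, spl$validation, arch, seed = 10, max_epochs = 50)
  a2 <- train_ann(spl$train, spl$validation, arch, seed = 10, max_epochs = 50)
  expect_identical(a1$layers, a2$layers)

  a0 <- train_ann(spl$train, spl$validation, arch, seed = 10, max_epochs = 0)
  expect_equal(nrow(a0$training_log), 0)
})

test_that("plain gradient descent at a small step has non-increasing loss", {
  ds <- generate_feature_dataset(30, seed = 7)
  spl <- split_dataset(ds$features, ds$labels, seed = 7)
  arch <- architecture(n_hidden = c(4, 8, 8), tf_hidden = rep("linear", 3),
                       tf_output = "linear", train_fn = "gradient_descent",
                       n_hidden_layers = 1)
  ann <- train_ann(spl$train, spl$validation, arch, seed = 2,
                   max_epochs = 120, patience = 120, learning_rate = 0.02)
  expect_true(all(diff(ann$training_log$train_loss) <= 1e-10))
})

test_that("forward pass matches a naive loop oracle on random networks", {
  set.seed(30)
  for (trial in 1:10) {
    arch <- random_architecture(seed = 300 + trial)
    ds <- generate_feature_dataset(10, seed = trial)
    spl <- split_dataset(ds$features, ds$labels, seed = trial)
    ann <- train_ann(spl$train, spl$validation, arch, seed = trial,
                     max_epochs = 3, patience = 3)
    x <- rnorm(24)
    names(x) <- colnames(ds$features)
    mine <- predict_grade(ann, x)$scores
    oracle <- naive_forward(ann, unname(x)[match(ann$input_schema, names(x))])
    expect_lt(max(abs(mine - oracle)), 1e-9)
  }
})

test_that("predict_grade reproduces a hand-computed single-layer forward", {
  arch <- architecture(n_hidden = c(2, 8, 8),
                       tf_hidden = rep("logistic_sigmoid", 3),
                       tf_output = "linear", train_fn = "gradient_descent",
                       n_hidden_layers = 1)
  ann <- structure(list(
    architecture = arch,
    layers = list(list(W = matrix(c(1, 0, 1, 0, 1, 1), 3, 2), b = c(0, 0.5)),
                  list(W = matrix(c(1, 0, 0, 1, -1, 1), 2, 3), b = c(0, 0, 0))),
    x_mu = c(0, 0, 0), x_sd = c(1, 1, 1),
    input_schema = c("a", "b", "c"),
    class_labels = c("1" = "excellent_good", "2" = "fair", "3" = "poor"),
    training_log = data.frame(), rng_seed = 1), class = "trained_ann")
  x <- c(a = 1, b = -1, c = 0.5)
  h <- 1 / (1 + exp(-c(1 * 1 + 0 * -1 + 1 * 0.5 + 0,
                       0 * 1 + 1 * -1 + 1 * 0.5 + 0.5)))
  y <- c(h[1], h[2], -h[1] + h[2])
  expected <- exp(y - max(y)) / sum(exp(y - max(y)))
  got <- predict_grade(ann, x)
  expect_equal(got$scores, expected, tolerance = 1e-12)
  expect_equal(got$grade, max(which(expected == max(expected))))
})

test_that("grade ties break toward the worse grade, argmax otherwise", {
  fake_scores <- function(s) {
    grade <- max(which(s == max(s)))
    grade
  }
  expect_equal(fake_scores(c(0.2, 0.2, 0.6)), 3)
  # exact tie through the real forward pass: identical weights for classes
  # 1 and 2
  arch <- architecture(n_hidden = c(1, 8, 8), tf_hidden = rep("linear", 3),
                       tf_output = "linear", train_fn = "gradient_descent",
                       n_hidden_layers = 1)
  ann <- structure(list(
    architecture = arch,
    layers = list(list(W = matrix(1, 1, 1), b = 0),
                  list(W = matrix(c(1, 1, 0), 1, 3), b = c(0, 0, -5))),
    x_mu = 0, x_sd = 1, input_schema = "a",
    class_labels = c("1" = "excellent_good", "2" = "fair", "3" = "poor"),
    training_log = data.frame(), rng_seed = 1), class = "trained_ann")
  expect_equal(predict_grade(ann, c(a = 2))$grade, 2)

  expect_error(predict_grade(ann, c(a = 1, b = 2)), "features")
})

test_that("ensemble mode follows majority with median fallback", {
  # three tiny constant networks with forced outputs
  const_ann <- function(target) {
    arch <- architecture(n_hidden = c(1, 8, 8), tf_hidden = rep("linear", 3),
                         tf_output = "linear", train_fn = "gradient_descent",
                         n_hidden_layers = 1)
    W2 <- matrix(0, 1, 3); W2[1, ] <- 0
    b2 <- c(-10, -10, -10); b2[target] <- 10
    structure(list(architecture = arch,
                   layers = list(list(W = matrix(0, 1, 1), b = 0),
                                 list(W = W2, b = b2)),
                   x_mu = 0, x_sd = 1, input_schema = "a",
                   class_labels = c("1" = "excellent_good", "2" = "fair",
                                    "3" = "poor"),
                   training_log = data.frame(), rng_seed = 1),
              class = "trained_ann")
  }
  x <- c(a = 0)
  p121 <- ensemble_predict(list(const_ann(1), const_ann(2), const_ann(1)), x)
  expect_equal(p121$mode_grade, 1)
  expect_equal(p121$final_grade, 1)

  p222 <- ensemble_predict(list(const_ann(2), const_ann(2), const_ann(2)), x)
  expect_equal(p222$mode_grade, 2)

  p123 <- ensemble_predict(list(const_ann(1), const_ann(2), const_ann(3)), x)
  expect_equal(p123$mode_grade, "no_consensus")
  expect_equal(p123$final_grade, 2)

  # permutation invariance of the mode
  p312 <- ensemble_predict(list(const_ann(3), const_ann(1), const_ann(2)), x)
  expect_equal(p312$mode_grade, p123$mode_grade)
  expect_equal(p312$final_grade, p123$final_grade)

  expect_error(ensemble_predict(list(const_ann(1), const_ann(2)), x),
               "exactly 3")
})

test_that("model JSON container round-trips weights and schema", {
  ds <- generate_feature_dataset(15, seed = 9)
  spl <- split_dataset(ds$features, ds$labels, seed = 9)
  arch <- architecture(n_hidden = c(5, 3, 8), train_fn = "rprop",
                       n_hidden_layers = 2)
  ann <- train_ann(spl$train, spl$validation, arch, seed = 4, max_epochs = 20)
  p <- tempfile(fileext = ".json")
  save_ann(ann, p)
  back <- load_ann(p)
  expect_equal(back$x_mu, ann$x_mu)
  expect_equal(back$input_schema, ann$input_schema)
  x <- rnorm(24); names(x) <- colnames(ds$features)
  expect_equal(predict_grade(back, x)$scores, predict_grade(ann, x)$scores,
               tolerance = 1e-12)
})

test_that("an independent learner confirms the synthetic classes separate", {
  skip_if_not_installed("nnet")
  ds <- generate_feature_dataset(60, separation = 6, seed = 12)
  spl <- split_dataset(ds$features, ds$labels, seed = 12)
  fit <- nnet::nnet(spl$train$x, nnet::class.ind(spl$train$y), size = 8,
                    softmax = TRUE, trace = FALSE, maxit = 200)
  pred <- max.col(predict(fit, spl$test$x))
  expect_gte(mean(pred == spl$test$y), 0.95)
})
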