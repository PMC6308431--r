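# Dataset splitting and the three-network mode-grading ensemble.

#' Stratified 70/15/15 split
#'
#' Splits a feature matrix and its grade labels into training (70%),
#' validation (15%) and test (15%) subsets, stratified by grade and
#' deterministic for a fixed seed. Every class must be present; each split
#' receives at least one sample per class.
#'
#' @param features N x K numeric matrix.
#' @param labels length-N grades (1, 2 or 3).
#' @param seed RNG seed.
#' @param proportions train/validation/test proportions (must sum to 1).
#' @return list of three lists `train`, `validation`, `test`, each with `x`,
#'   `y` and `idx` (row indices into the input).
#' @export
split_dataset <- function(features, labels, seed = 1L,
                          proportions = c(0.70, 0.15, 0.15)) {
  stopifnot(nrow(features) == length(labels),
            abs(sum(proportions) - 1) < 1e-9)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 3)
    stop("stratification error: all 3 grade classes must be present")
  set.seed(seed)
  idx <- list(train = integer(), validation = integer(), test = integer())
  for (cl in classes) {
    rows <- sample(which(labels == cl))
    n <- length(rows)
    n_va <- max(1L, round(proportions[2] * n))
    n_te <- max(1L, round(proportions[3] * n))
    n_tr <- n - n_va - n_te
    if (n_tr < 1) stop("class ", cl, " too small to stratify (n = ", n, ")")
    idx$train <- c(idx$train, rows[seq_len(n_tr)])
    idx$validation <- c(idx$validation, rows[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, rows[n_tr + n_va + seq_len(n_te)])
  }
  lapply(idx, function(i)
    list(x = features[i, , drop = FALSE], y = labels[i], idx = i))
}

#' Ensemble prediction by mode of three networks
#'
#' Each of the three independent networks grades the input; the ensemble
#' grade is the mode when at least two agree. On full three-way disagreement
#' the mode is undefined (`no_consensus`) and the final grade falls back to
#' the median of the three ordinal grades.
#'
#' @param anns list of exactly 3 `trained_ann` objects sharing one input
#'   schema.
#' @param x reduced feature vector (or 1-row matrix).
#' @return a `grade_prediction`: `per_ann` (3 grades), `per_ann_scores`
#'   (3 x 3), `mode_grade` (grade or `"no_consensus"`) and `final_grade`.
#' @export
ensemble_predict <- function(anns, x) {
  if (length(anns) != 3) stop("ensemble requires exactly 3 networks")
  schemas <- lapply(anns, `[[`, "input_schema")
  if (!all(vapply(schemas, identical, logical(1), y = schemas[[1]])))
    stop("the 3 networks must share one input schema")
  preds <- lapply(anns, predict_grade, x = x)
  grades <- vapply(preds, `[[`, numeric(1), "grade")
  scores <- do.call(rbind, lapply(preds, `[[`, "scores"))
  tab <- tabulate(grades, nbins = 3)
  if (max(tab) >= 2) {
    mode_grade <- which.max(tab)
    final <- mode_grade
  } else {
    mode_grade <- "no_consensus"
    final <- sort(grades)[2]  # median of three distinct ordinal grades
  }
  structure(list(per_ann = grades, per_ann_scores = scores,
                 mode_grade = mode_grade, final_grade = final),
            class = "grade_prediction")
}

#' @export
print.grade_prediction <- function(x, ...) {
  cat("<grade_prediction> per-ANN:", paste(x$per_ann, collapse = ","),
      "| mode:", x$mode_grade, "| final:", x$final_grade, "\n")
  invisible(x)
}

#' Accuracy of a trained network on a split
#'
#' @param ann a `trained_ann`.
#' @param split one element of [split_dataset()] output (`x`, `y`).
#' @return proportion of exact grade matches.
#' @export
ann_accuracy <- function(ann, split) {
  pred <- apply(split$x, 1, function(row) predict_grade(ann, row)$grade)
  mean(pred == split$y)
}

#' Train the three-network grading ensemble
#'
#' Trains one network per architecture (three architectures, typically the
#' three fittest chromosomes of a genetic search) on the same split, with
#' per-network seeds derived from `seed`.
#'
#' @param split output of [split_dataset()].
#' @param archs list of 3 `ann_architecture` objects.
#' @param seed base RNG seed.
#' @param ... passed to [train_ann()].
#' @return list of 3 `trained_ann` objects.
#' @export
train_ensemble <- function(split, archs, seed = 1L, ...) {
  stopifnot(length(archs) == 3)
  lapply(seq_along(archs), function(i)
    train_ann(split$train, split$validation, archs[[i]],
              seed = seed + i, ...))
}
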