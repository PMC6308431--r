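# Frequency comparisons of segmentation/grading outcomes.
#
# Two-sided Fisher convention: the sum of hypergeometric point probabilities
# no larger than the observed table's (the convention of stats::fisher.test,
# recorded explicitly because two-sided Fisher definitions vary).

#' Build a labeled contingency table
#'
#' @param counts matrix (or vector coercible to one) of non-negative integer
#'   counts, at least 2 x 2.
#' @param row_labels,col_labels optional dimension labels.
#' @return integer matrix with dimnames.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(col_labels)) colnames(m) <- col_labels
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param t 2x2 matrix of counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2))) stop("fisher_exact_2x2 requires a 2x2 table")
  stats::fisher.test(t)$p.value
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; expected counts from the table margins;
#' df = (R-1)(C-1).
#'
#' @param t R x C matrix of counts with all expected counts > 0.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(t) {
  t <- as.matrix(t)
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(expected <= 0)) stop("degenerate table: zero expected count")
  res <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Agreement rate between paired gradings
#'
#' @param predictions,reference equal-length grade vectors.
#' @return list with `rate`, `matches`, `n` and a formatted `label`
#'   ("x/n (p%)").
#' @export
agreement_rate <- function(predictions, reference) {
  if (length(predictions) != length(reference))
    stop("pairing error: gradings have different lengths")
  matches <- sum(predictions == reference)
  n <- length(reference)
  list(rate = matches / n, matches = matches, n = n,
       label = sprintf("%d/%d (%.1f%%)", matches, n, 100 * matches / n))
}

#' Read a contingency table from a small CSV
#'
#' First column = row labels, remaining columns = counts.
#'
#' @param path CSV path.
#' @return labeled contingency table.
#' @export
read_contingency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  contingency_table(as.matrix(df[, -1, drop = FALSE]),
                    row_labels = df[[1]], col_labels = colnames(df)[-1])
}

#' Emit a test result as JSON
#'
#' @param result list from [chi_square_test()] or a Fisher p-value.
#' @param method label recorded in the JSON.
#' @param path optional output file.
#' @return JSON string.
#' @export
stats_result_json <- function(result, method, path = NULL) {
  if (is.numeric(result) && length(result) == 1)
    result <- list(p_value = result)
  js <- jsonlite::toJSON(c(list(method = method), result),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  js
}
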