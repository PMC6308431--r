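# Collinearity pruning by iterated variance inflation factors.
#
# VIF_k = 1 / (1 - R^2_k), R^2_k from the least-squares regression (with
# intercept) of column k on all remaining columns. One column — the one with
# the largest VIF above the threshold — is removed per iteration until all
# surviving columns have VIF <= threshold. Read against the pipeline's
# 36 -> 24 reduction: 12 removal iterations plus one final confirmation pass.

#' Variance inflation factor of one column
#'
#' @param feature_matrix numeric N x K matrix (N > K >= 2), no constant
#'   columns.
#' @param col column index.
#' @return the VIF; `Inf` when the column is perfectly collinear with the
#'   others (1 - R^2 below 1e-12).
#' @export
vif <- function(feature_matrix, col) {
  X <- as.matrix(feature_matrix)
  if (ncol(X) < 2) stop("need at least 2 columns")
  if (nrow(X) <= ncol(X)) stop("ill-posed: need more rows than columns")
  y <- X[, col]
  Z <- cbind(1, X[, -col, drop = FALSE])
  fit <- stats::lm.fit(Z, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("constant column ", col)
  r2 <- 1 - rss / tss
  if (1 - r2 < 1e-12) return(Inf)
  1 / (1 - r2)
}

# VIFs of every column.
vif_all <- function(X) {
  vapply(seq_len(ncol(X)), function(k) vif(X, k), numeric(1))
}

#' Iterated VIF pruning of a feature matrix
#'
#' Repeatedly removes the single column with the largest VIF strictly above
#' `threshold` (ties broken toward the earlier column in schema order) and
#' recomputes, stopping when the maximum VIF is at or below the threshold.
#'
#' @param feature_matrix numeric matrix with named columns (typically N x 36).
#' @param threshold collinearity cut (default 10).
#' @return list with `kept_names` (surviving columns, schema order),
#'   `report` (a `vif_report`: per-iteration removals and final VIFs) and
#'   `n_iterations` (removals plus the final confirmation pass).
#' @export
vif_prune <- function(feature_matrix, threshold = 10) {
  X <- as.matrix(feature_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  removed <- character(0)
  removed_vif <- numeric(0)
  repeat {
    if (nrow(X) <= ncol(X))
      stop("ill-posed: fewer rows than surviving columns (",
           nrow(X), " x ", ncol(X), ")")
    v <- vif_all(X)
    worst <- which.max(v)  # first index on ties = earlier schema position
    if (v[worst] <= threshold) break
    removed <- c(removed, colnames(X)[worst])
    removed_vif <- c(removed_vif, v[worst])
    X <- X[, -worst, drop = FALSE]
  }
  report <- structure(
    list(iterations = data.frame(removed_name = removed,
                                 vif_value = removed_vif),
         final_vifs = stats::setNames(v, colnames(X)),
         threshold = threshold),
    class = "vif_report")
  list(kept_names = colnames(X), report = report,
       n_iterations = length(removed) + 1L)
}

#' @export
print.vif_report <- function(x, ...) {
  cat("<vif_report>", nrow(x$iterations), "removals, final max VIF",
      sprintf("%.2f", max(x$final_vifs)), "(threshold", x$threshold, ")\n")
  if (nrow(x$iterations) > 0) print(x$iterations)
  invisible(x)
}

#' Serialize a VIF report to JSON
#'
#' @param report a `vif_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
vif_report_json <- function(report, path = NULL) {
  obj <- list(iterations = report$iterations,
              final_vifs = as.list(report$final_vifs),
              threshold = report$threshold)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
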