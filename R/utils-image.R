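#' @useDynLib blastograde, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Intensity matrices are numeric [H rows x W cols] in [0, 255], 0-based pixel
# indexing only at the C++ boundary; everywhere in R, 1-based (row, col).

#' Extract the pixel matrix from any image-like object
#'
#' Accepts a plain matrix, a `raw_image`, or a `std_image` and returns the
#' underlying intensity matrix (rows x cols, values in \[0, 255\]).
#'
#' @param x image-like object.
#' @return numeric matrix.
#' @export
as_pixels <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "std_image") || inherits(x, "raw_image")) {
    p <- x$pixels
    if (is.matrix(p)) return(p)
    stop("object does not hold a single-channel pixel matrix; ",
         "call to_grayscale() first")
  }
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as an image")
}

# Shift a matrix by (dr, dc) with replicated borders.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Min-max rescale to [0, 255]; constant input maps to all zeros.
rescale_minmax <- function(m) {
  rng <- range(m)
  if (rng[2] <= rng[1]) return(array(0, dim(m)))
  (m - rng[1]) / (rng[2] - rng[1]) * 255
}

# --- separable resampling -------------------------------------------------

# Cubic Lagrange weights through nodes -1, 0, 1, 2 at fractional position t.
# These reproduce any polynomial of degree <= 3 exactly, which is the
# defining property of the f(x,y) = sum a_ij x^i y^j patch interpolant.
lagrange_cubic_weights <- function(t) {
  cbind(-t * (t - 1) * (t - 2) / 6,
        (t + 1) * (t - 1) * (t - 2) / 2,
        -t * (t + 1) * (t - 2) / 2,
        t * (t + 1) * (t - 1) / 6)
}

linear_weights <- function(t) cbind(1 - t, t)

# Resample one dimension (rows) of a matrix to out_n samples.
# Pixel-center alignment: output center k maps to source (k - 0.5)/scale + 0.5.
resample_rows <- function(m, out_n, method) {
  in_n <- nrow(m)
  scale <- out_n / in_n
  s <- (seq_len(out_n) - 0.5) / scale + 0.5
  base <- floor(s)
  t <- s - base
  if (method == "bicubic") {
    w <- lagrange_cubic_weights(t)
    taps <- -1L:2L
  } else {
    w <- linear_weights(t)
    taps <- 0L:1L
  }
  out <- matrix(0, out_n, ncol(m))
  for (k in seq_along(taps)) {
    idx <- pmin(pmax(base + taps[k], 1L), in_n)  # clamped replication at edges
    out <- out + m[idx, , drop = FALSE] * w[, k]
  }
  out
}

# Full 2-D separable resample.
resample_image <- function(m, out_h, out_w, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  m <- resample_rows(m, out_h, method)
  t(resample_rows(t(m), out_w, method))
}

# Sobel 3x3 derivative pair, replicated borders. Returns list(gx, gy).
sobel_pair <- function(m) {
  # horizontal derivative (columns direction)
  gx <- (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) * 2 +
    (shift_mat(m, -1, -1) - shift_mat(m, -1, 1)) +
    (shift_mat(m, 1, -1) - shift_mat(m, 1, 1))
  gy <- (shift_mat(m, -1, 0) - shift_mat(m, 1, 0)) * 2 +
    (shift_mat(m, -1, -1) - shift_mat(m, 1, -1)) +
    (shift_mat(m, -1, 1) - shift_mat(m, 1, 1))
  list(gx = gx, gy = gy)
}

# Squared distance of every pixel from a center (row, col).
dist2_from <- function(nr, nc, center_row, center_col) {
  dr <- (seq_len(nr) - center_row)^2
  dc <- (seq_len(nc) - center_col)^2
  outer(dr, dc, `+`)
}

# Boolean disk mask, inclusive boundary (distance <= radius).
disk_mask <- function(nr, nc, center_row, center_col, radius) {
  dist2_from(nr, nc, center_row, center_col) <= radius^2
}

#' Write a boolean mask or intensity matrix as an 8-bit PNG
#'
#' @param m logical or numeric matrix (numeric assumed in \[0, 255\]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(m, path) {
  if (is.logical(m)) m <- m * 255
  png::writePNG(pmin(pmax(m, 0), 255) / 255, path)
  invisible(path)
}
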