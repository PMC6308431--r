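# Grey-level co-occurrence matrices and their Haralick statistics.
#
# Quantization: 8 levels over [0, 255] (bin width 32), distance 1, the four
# standard angles; region statistics average the four angles. Pairs are
# counted symmetrically and only when BOTH pixels are inside the region mask.

GLCM_LEVELS <- 8L

glcm_offset <- function(angle, distance) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Grey-level co-occurrence matrix of a masked region
#'
#' Counts in-mask pixel pairs at the given distance and angle after uniform
#' quantization of \[0, 255\] into `levels` bins. Accumulation is symmetric:
#' each pair is counted in both directions. Pairs with either pixel outside
#' the mask are excluded.
#'
#' @param region_image intensity matrix in \[0, 255\].
#' @param distance pair offset in pixels (default 1).
#' @param angle one of 0, 45, 90, 135 degrees.
#' @param levels number of quantization levels (default 8).
#' @param mask logical matrix of in-region pixels; `NULL` means all pixels.
#' @param normalize divide by the total count so entries sum to 1.
#' @return a `glcm`: levels x levels matrix with attributes `distance`,
#'   `angle`, `normalized`.
#' @export
glcm_compute <- function(region_image, distance = 1L, angle = 0,
                         levels = GLCM_LEVELS, mask = NULL,
                         normalize = TRUE) {
  m <- as_pixels(region_image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  if (sum(mask) < 2) stop("empty region: need at least 2 in-mask pixels")
  off <- glcm_offset(angle, as.integer(distance))
  lev <- pmin(pmax(floor(m / (256 / levels)), 0), levels - 1)

  nr <- nrow(m); nc <- ncol(m)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a_lev <- lev[r1, c1, drop = FALSE]
  b_lev <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] &
    mask[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- tabulate(a_lev[ok] * levels + b_lev[ok] + 1L, nbins = levels^2)
  g <- matrix(counts, levels, levels, byrow = TRUE)
  g <- g + t(g)  # symmetric accumulation
  if (normalize && sum(g) > 0) g <- g / sum(g)
  structure(g, distance = distance, angle = angle, normalized = normalize,
            class = c("glcm", "matrix"))
}

#' Haralick statistics of a normalized GLCM
#'
#' contrast = sum p(i,j) (i-j)^2; energy = sum p^2; homogeneity =
#' sum p / (1 + |i-j|); entropy = -sum p log2 p (with 0 log 0 = 0);
#' correlation is the normalized covariance of the marginals (0 when either
#' marginal is degenerate).
#'
#' @param g a normalized `glcm`.
#' @return named numeric vector (contrast, correlation, energy, homogeneity,
#'   entropy).
#' @export
glcm_stats <- function(g) {
  if (!isTRUE(attr(g, "normalized")) || abs(sum(g) - 1) > 1e-9)
    stop("glcm_stats requires a normalized GLCM")
  L <- nrow(g)
  i <- matrix(seq_len(L), L, L)          # row index
  j <- t(i)
  p <- unclass(g)
  contrast <- sum(p * (i - j)^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  correlation <- if (var_i <= 1e-12 || var_j <= 1e-12) 0 else
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

# Mean of the five GLCM statistics over the four standard angles.
glcm_region_stats <- function(region_image, mask, distance = 1L,
                              levels = GLCM_LEVELS) {
  stats_by_angle <- vapply(c(0, 45, 90, 135), function(a) {
    glcm_stats(glcm_compute(region_image, distance, a, levels, mask))
  }, numeric(5))
  rowMeans(stats_by_angle)
}
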