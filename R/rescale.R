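# The scaling algorithm for smartphone-through-ocular captures.
#
# Small embryos (well under the 100 px floor of the main two-stage search)
# are located by a variable-range circular Hough sweep on the equalized,
# contrast-magnified, binarized image — or by a watershed of the distance
# transform when the Hough fails — then cropped and expanded by bicubic
# interpolation (f(x,y) = sum_{i,j<=3} a_ij x^i y^j on each 4x4 neighborhood)
# onto the canonical 640x480 canvas so the main pipeline can process them.

VARIABLE_RANGE_WINDOWS <- list(c(8, 20), c(20, 45), c(45, 75), c(75, 100))
RESCALE_TARGET_RADIUS <- 150
MAX_SCALE_FACTOR <- 20

#' Global histogram equalization
#'
#' Standard cumulative-distribution mapping of an 8-bit grayscale image;
#' constant input passes through unchanged.
#'
#' @param img single-channel intensity matrix in \[0, 255\].
#' @return equalized matrix in \[0, 255\].
#' @export
equalize_histogram <- function(img) {
  m <- round(as_pixels(img))
  h <- tabulate(m + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(m)
  if (n == cdf_min) return(m)  # constant image: degenerate CDF
  map <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  matrix(map[m + 1L], nrow(m), ncol(m))
}

# 5-point box smoothing, `passes` times (pixel-noise suppression before
# thresholding).
box_smooth <- function(m, passes = 3L) {
  for (i in seq_len(passes))
    m <- (m + shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
            shift_mat(m, 0, 1) + shift_mat(m, 0, -1)) / 5
  m
}

largest_component_size <- function(mask) {
  if (!any(mask)) return(0L)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  max(tabulate(lab[lab > 0]))
}

#' Contrast magnification and binarization
#'
#' Linear contrast stretch with 2% symmetric saturation and light box
#' smoothing, followed by an Otsu threshold; polarity is normalized so that
#' the foreground is the minority class. When the Otsu split leaves an
#' implausibly large foreground for a smartphone-regime embryo (over 15% of
#' the frame, the signature of a threshold landing inside the background
#' noise rather than between background and embryo), the binarization falls
#' back to the 1% intensity tails, keeping whichever tail forms the more
#' spatially coherent mass (larger single connected component). A constant
#' image yields an all-`FALSE` mask.
#'
#' @param img equalized grayscale matrix in \[0, 255\].
#' @param max_fg_frac foreground fraction above which the Otsu split is
#'   deemed degenerate (default 0.15).
#' @return logical foreground mask.
#' @export
contrast_magnify_binarize <- function(img, max_fg_frac = 0.15) {
  m <- stretch_saturate(as_pixels(img), 0.02)
  if (max(m) <= min(m)) return(matrix(FALSE, nrow(m), ncol(m)))
  sm <- box_smooth(m)
  thr <- EBImage::otsu(EBImage::Image(t(sm) / 255), range = c(0, 1)) * 255
  mask <- sm > thr
  if (mean(mask) > 0.5) mask <- !mask  # foreground = minority class
  if (mean(mask) > max_fg_frac) {
    q <- stats::quantile(sm, c(0.01, 0.99), names = FALSE)
    hi <- sm >= q[2]
    lo <- sm <= q[1]
    mask <- if (largest_component_size(hi) >= largest_component_size(lo))
      hi else lo
  }
  mask
}

# Boundary pixels of a boolean mask (pixels with a FALSE 4-neighbor).
mask_boundary <- function(mask) {
  inner <- mask &
    shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
    shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1)
  mask & !inner
}

#' Variable-range circular Hough detection for small embryos
#'
#' Sweeps the radius windows 8--20, 20--45, 45--75 and 75--100 px over the
#' boundary pixels of the binary mask, keeps the best candidate per window
#' and returns the overall strongest above the strength floor.
#'
#' @param binary logical foreground mask.
#' @param min_strength acceptance floor on normalized vote strength.
#' @param windows list of radius windows (defaults above).
#' @return a `circle_detection` with stage `"rescue_variable_range"`, or
#'   `NULL`.
#' @export
variable_range_hough <- function(binary, min_strength = 0.25,
                                 windows = VARIABLE_RANGE_WINDOWS) {
  edges <- mask_boundary(binary)
  if (!any(edges)) return(NULL)
  best <- NULL
  for (w in windows) {
    cand <- hough_circles(edges, w[1], w[2], r_step = 1,
                          stage = "rescue_variable_range")
    if (nrow(cand) == 0) next
    top <- cand[1, ]
    if (top$strength < min_strength) next
    if (is.null(best) || top$strength > best$strength)
      best <- new_circle_detection(top$center_row, top$center_col,
                                   top$radius, top$strength,
                                   "rescue_variable_range")
  }
  best
}

#' Watershed fallback localization
#'
#' When the variable-range Hough fails, the Euclidean distance transform of
#' the foreground is flooded by the watershed transform; candidate regions
#' are scored by circularity (4 pi A / P^2) and the best region with
#' circularity >= 0.6 and area >= 50 px is returned.
#'
#' @param binary logical foreground mask.
#' @param min_circularity,min_area acceptance thresholds.
#' @return list with `mask` (logical matrix), `center_row`, `center_col`,
#'   `radius` (equivalent-disk radius sqrt(A/pi)), `circularity`; or `NULL`.
#' @export
watershed_fallback <- function(binary, min_circularity = 0.6, min_area = 50) {
  if (!any(binary)) return(NULL)
  eb <- EBImage::Image(t(binary))
  dm <- EBImage::distmap(eb)
  ws <- EBImage::watershed(dm)
  labels <- t(EBImage::imageData(ws))
  shp <- EBImage::computeFeatures.shape(ws)
  if (is.null(shp) || nrow(shp) == 0) return(NULL)
  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1.5)
  ok <- circ >= min_circularity & area >= min_area
  if (!any(ok)) return(NULL)
  pick <- which(ok)[which.max(circ[ok] * log(area[ok]))]
  mask <- labels == pick
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  list(mask = mask,
       center_row = mean(rows), center_col = mean(cols),
       radius = sqrt(sum(mask) / pi),
       circularity = unname(circ[pick]))
}

#' Bicubic expansion of an image crop
#'
#' Crops `img` to `crop_box` and resamples on the scaled grid. Each output
#' sample evaluates the bicubic surface f(x,y) = sum_{i,j=0..3} a_ij x^i y^j
#' fitted through its 4x4 source neighborhood (edge handling by clamped
#' replication), which reproduces any polynomial of degree <= 3 exactly.
#'
#' @param img intensity matrix.
#' @param crop_box integer vector (row_min, row_max, col_min, col_max).
#' @param scale_factor expansion factor (> 1).
#' @param clip clip the result to \[0, 255\] (disable to verify polynomial
#'   exactness).
#' @return expanded intensity matrix.
#' @export
bicubic_expand <- function(img, crop_box, scale_factor, clip = TRUE) {
  stopifnot(scale_factor > 1)
  m <- as_pixels(img)
  crop_box <- round(crop_box)
  crop_box[c(1, 3)] <- pmax(crop_box[c(1, 3)], 1)
  crop_box[2] <- min(crop_box[2], nrow(m))
  crop_box[4] <- min(crop_box[4], ncol(m))
  crop <- m[crop_box[1]:crop_box[2], crop_box[3]:crop_box[4], drop = FALSE]
  if (nrow(crop) <= 4 || ncol(crop) <= 4)
    stop("degenerate crop: needs more than 4 px per side")
  out <- resample_image(crop, round(nrow(crop) * scale_factor),
                        round(ncol(crop) * scale_factor), "bicubic")
  if (clip) out <- pmin(pmax(out, 0), 255)
  out
}

#' Rescue a smartphone-regime image by the scaling algorithm
#'
#' Grayscale conversion, histogram equalization, contrast magnification and
#' binarization, then embryo localization by [variable_range_hough()] with
#' [watershed_fallback()] as the second chance. On success the source is
#' cropped to a box of three detected radii around the center, expanded by
#' [bicubic_expand()] so the embryo radius reaches `target_radius`, and
#' centered on a 640x480 canvas padded with the crop's median border value.
#'
#' @param raw a `raw_image` (or grayscale matrix) in the smartphone regime.
#' @param target_radius embryo radius after expansion (default 150 px, the
#'   midpoint of the main pipeline's Hough windows).
#' @param crop_radii crop box half-width in units of the detected radius
#'   (default 1.5, i.e. a box of 3 radii per side).
#' @param min_strength strength floor for the variable-range Hough.
#' @return a `rescale_result`: `found_by` (`"hough_variable_range"`,
#'   `"watershed_fallback"` or `"not_found"`), `small_circle`, `crop_box`,
#'   `scale_factor`, `output` (a `std_image` when found) and `map_point`, a
#'   function mapping source (row, col) to output coordinates.
#' @export
rescale_image <- function(raw, target_radius = RESCALE_TARGET_RADIUS,
                          crop_radii = 1.5, min_strength = 0.25) {
  gray <- to_grayscale(raw)
  eq <- equalize_histogram(gray)  # brightness-corrected view (kept for QC)
  # Thresholding uses the contrast-magnified raw intensities: equalization
  # maps the dominant background mode across most of the intensity range,
  # which defeats any global threshold on a mostly-background frame.
  binary <- contrast_magnify_binarize(gray)
  found_by <- "hough_variable_range"
  circ <- variable_range_hough(binary, min_strength = min_strength)
  if (is.null(circ)) {
    ws <- watershed_fallback(binary)
    if (is.null(ws))
      return(structure(list(found_by = "not_found", small_circle = NULL,
                            crop_box = NULL, scale_factor = NA_real_,
                            output = NULL),
                       class = "rescale_result"))
    found_by <- "watershed_fallback"
    circ <- new_circle_detection(ws$center_row, ws$center_col, ws$radius,
                                 ws$circularity, "rescue_variable_range")
  }
  scale_factor <- min(target_radius / circ$radius, MAX_SCALE_FACTOR)
  if (scale_factor <= 1) scale_factor <- 1.0001  # already large enough
  half <- crop_radii * circ$radius
  crop_box <- c(round(circ$center_row - half), round(circ$center_row + half),
                round(circ$center_col - half), round(circ$center_col + half))
  expanded <- bicubic_expand(gray, crop_box, scale_factor)
  # place centered on the canonical canvas
  out_h <- 480L; out_w <- 640L
  border <- c(expanded[1, ], expanded[nrow(expanded), ],
              expanded[, 1], expanded[, ncol(expanded)])
  canvas <- matrix(stats::median(border), out_h, out_w)
  src_rows <- nrow(expanded); src_cols <- ncol(expanded)
  # overlap of the expanded image with the canvas, both centered
  r0 <- max(1L, (src_rows - out_h) %/% 2L + 1L)
  c0 <- max(1L, (src_cols - out_w) %/% 2L + 1L)
  rows_take <- r0:min(src_rows, r0 + out_h - 1L)
  cols_take <- c0:min(src_cols, c0 + out_w - 1L)
  dr0 <- (out_h - length(rows_take)) %/% 2L
  dc0 <- (out_w - length(cols_take)) %/% 2L
  canvas[dr0 + seq_along(rows_take), dc0 + seq_along(cols_take)] <-
    expanded[rows_take, cols_take]
  out <- structure(list(pixels = round(canvas),
                        saturation_fraction = NA_real_,
                        pad = c(top = 0L, bottom = 0L, left = 0L, right = 0L),
                        provenance = "rescaled"),
                   class = "std_image")
  # effective crop origin after clamping inside bicubic_expand
  cb <- round(crop_box)
  cb[c(1, 3)] <- pmax(cb[c(1, 3)], 1)
  map_point <- function(row, col) {
    # source -> crop -> expanded (pixel-center alignment) -> canvas
    er <- (row - cb[1] + 0.5) * scale_factor + 0.5
    ec <- (col - cb[3] + 0.5) * scale_factor + 0.5
    c(row = er - (r0 - 1) + dr0, col = ec - (c0 - 1) + dc0)
  }
  structure(list(found_by = found_by, small_circle = circ,
                 crop_box = cb, scale_factor = scale_factor,
                 output = out, map_point = map_point),
            class = "rescale_result")
}

#' @export
print.rescale_result <- function(x, ...) {
  cat("<rescale_result>", x$found_by)
  if (!is.null(x$small_circle))
    cat(sprintf(" | r=%.1f at (%.0f, %.0f), scale %.2f", x$small_circle$radius,
                x$small_circle$center_row, x$small_circle$center_col,
                x$scale_factor))
  cat("\n")
  invisible(x)
}

#' Write a rescale result (PNG + JSON sidecar)
#'
#' @param res a `rescale_result` with an output image.
#' @param png_path output PNG path; sidecar JSON is written next to it.
#' @return `png_path`, invisibly.
#' @export
write_rescale_result <- function(res, png_path) {
  if (is.null(res$output)) stop("no output image: embryo was not found")
  write_image_png(res$output$pixels, png_path)
  side <- list(found_by = res$found_by,
               crop_box = res$crop_box,
               scale_factor = res$scale_factor,
               circle = if (!is.null(res$small_circle))
                 circle_record(res$small_circle))
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             paste0(tools::file_path_sans_ext(png_path), ".json"))
  invisible(png_path)
}
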