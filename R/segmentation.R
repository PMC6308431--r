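# Embryo segmentation: gradient magnitude -> fixed-threshold binarization ->
# two-stage circular Hough detection -> ER/RR/TE region isolation.
#
# ER = detected circle grown by 5 px (keeps the zona pellucida),
# RR = detected circle shrunk by 40 px (inner cell mass + blastocoel),
# TE = ER minus RR (the trophectoderm annulus). The +5/-40 offsets are the
# pipeline's fixed region constants, overridable through the config.

ER_GROW_PX <- 5
RR_SHRINK_PX <- 40

#' Gradient magnitude of a standardized image
#'
#' Per-pixel Euclidean magnitude of the 3x3 Sobel derivative pair, with
#' replicated borders, so edges are highlighted in all directions.
#'
#' @param img a `std_image` or intensity matrix.
#' @return non-negative numeric matrix of the same size.
#' @export
gradient_magnitude <- function(img) {
  m <- as_pixels(img)
  g <- sobel_pair(m)
  sqrt(g$gx^2 + g$gy^2)
}

#' Threshold an array into a boolean edge map
#'
#' The gradient magnitude is min-max rescaled to \[0, 255\] per image (so the
#' fixed threshold is meaningful across exposures) and thresholded at
#' `threshold`, inclusive (value >= threshold is `TRUE`).
#'
#' @param arr numeric array (any non-negative scale; rescaled internally when
#'   `rescale = TRUE`).
#' @param threshold intensity cut, default 128.
#' @param rescale min-max rescale to \[0, 255\] first (default `TRUE`).
#' @return logical matrix.
#' @export
binarize <- function(arr, threshold = 128, rescale = TRUE) {
  if (rescale) arr <- rescale_minmax(arr)
  arr >= threshold
}

#' Circular Hough transform over a radius range
#'
#' Every `TRUE` pixel votes for all centers at distance `r`; the best
#' accumulator cell per radius becomes a candidate. Strength is the vote
#' count normalized by the ideal full-circle vote count for that radius.
#'
#' @param binary logical matrix of edge pixels.
#' @param r_min,r_max inclusive radius range in pixels (`r_min < r_max`).
#' @param r_step radius sampling step (default 2; candidates are refined to
#'   single-pixel resolution by [two_stage_detect()]).
#' @param stage label recorded on the returned candidates.
#' @return data.frame of candidates ordered by decreasing strength, with
#'   columns `center_row`, `center_col`, `radius`, `strength`, `stage`.
#' @export
hough_circles <- function(binary, r_min, r_max, r_step = 2,
                          stage = "custom") {
  if (r_min >= r_max) stop("r_min must be < r_max")
  idx <- which(binary) - 1L
  nr <- nrow(binary)
  if (length(idx) == 0)
    return(data.frame(center_row = integer(), center_col = integer(),
                      radius = integer(), strength = numeric(),
                      stage = character()))
  radii <- as.integer(seq(r_min, r_max, by = r_step))
  acc <- hough_accumulate(idx %% nr, idx %/% nr, nr, ncol(binary), radii)
  out <- data.frame(center_row = acc$row + 1L, center_col = acc$col + 1L,
                    radius = acc$radius,
                    strength = acc$votes / acc$ring_size,
                    stage = stage)
  out[order(-out$strength, -out$radius), , drop = FALSE]
}

new_circle_detection <- function(center_row, center_col, radius, strength,
                                 stage) {
  structure(list(center_row = center_row, center_col = center_col,
                 radius = radius, strength = strength, stage = stage),
            class = "circle_detection")
}

#' @export
print.circle_detection <- function(x, ...) {
  cat(sprintf("<circle> center (%.0f, %.0f)  radius %.0f  strength %.3f  [%s]\n",
              x$center_row, x$center_col, x$radius, x$strength, x$stage))
  invisible(x)
}

# Refine a candidate to single-pixel radius resolution around r0.
refine_candidate <- function(binary, r0, r_lo, r_hi, stage) {
  radii <- max(r_lo, r0 - 2):min(r_hi, r0 + 2)
  idx <- which(binary) - 1L
  nr <- nrow(binary)
  acc <- hough_accumulate(idx %% nr, idx %/% nr, nr, ncol(binary),
                          as.integer(radii))
  s <- acc$votes / acc$ring_size
  best <- order(-s, -acc$radius)[1]
  new_circle_detection(acc$row[best] + 1L, acc$col[best] + 1L,
                       acc$radius[best], s[best], stage)
}

#' Two-stage embryo circle detection
#'
#' Searches radii 100--150 px (initial blastocysts) and then 150--200 px
#' (expanded blastocysts); the best candidate of each stage is compared by
#' strength, ties broken toward the larger radius. Candidates below
#' `min_strength` (fraction of the ideal full-circle vote count) are
#' rejected, so a blank or sub-100-px embryo yields no detection.
#'
#' @param binary logical edge map from [binarize()].
#' @param min_strength acceptance floor on normalized strength (default 0.25).
#' @param r_step coarse search step in pixels (refined to step 1 afterwards).
#' @return a `circle_detection`, or `NULL` when neither stage finds an
#'   acceptable circle.
#' @export
two_stage_detect <- function(binary, min_strength = 0.25, r_step = 2) {
  stages <- list(stage1_100_150 = c(100, 150), stage2_150_200 = c(151, 200))
  best <- NULL
  for (nm in names(stages)) {
    rng <- stages[[nm]]
    cand <- hough_circles(binary, rng[1], rng[2], r_step = r_step, stage = nm)
    if (nrow(cand) == 0) next
    top <- refine_candidate(binary, cand$radius[1], rng[1], rng[2], nm)
    if (top$strength < min_strength) next
    if (is.null(best) ||
        top$strength > best$strength ||
        (top$strength == best$strength && top$radius > best$radius))
      best <- top
  }
  best
}

#' Isolate the ER, RR and TE regions around a detected circle
#'
#' ER is the detected disk grown by 5 px (zona pellucida included), RR the
#' disk shrunk by 40 px (inner cell mass and blastocoel), TE the set
#' difference (trophectoderm annulus). Masked images keep original
#' intensities inside the mask and 0 outside.
#'
#' @param img `std_image` or intensity matrix.
#' @param circle a `circle_detection`.
#' @param truth optional ground-truth circle (list with `center_row`,
#'   `center_col`, `radius`) used by [classify_status()].
#' @param fill_threshold passed to [classify_status()].
#' @return a `segmentation_result` with masks, masked images, radii and
#'   status (`"full"`, `"partial"` or `"none"`).
#' @export
isolate_regions <- function(img, circle, truth = NULL, fill_threshold = 0.8) {
  m <- as_pixels(img)
  if (is.null(circle)) {
    res <- structure(list(circle = NULL, status = "none"),
                     class = "segmentation_result")
    return(res)
  }
  if (circle$radius <= RR_SHRINK_PX)
    stop("degenerate region: circle radius ", circle$radius,
         " must exceed ", RR_SHRINK_PX, " px")
  nr <- nrow(m); nc <- ncol(m)
  er_radius <- circle$radius + ER_GROW_PX
  rr_radius <- circle$radius - RR_SHRINK_PX
  er <- disk_mask(nr, nc, circle$center_row, circle$center_col, er_radius)
  rr <- disk_mask(nr, nc, circle$center_row, circle$center_col, rr_radius)
  te <- er & !rr
  res <- structure(list(circle = circle,
                        er_mask = er, rr_mask = rr, te_mask = te,
                        er_image = m * er, rr_image = m * rr,
                        te_image = m * te,
                        er_radius = er_radius, rr_radius = rr_radius,
                        image = m, status = NA_character_),
                   class = "segmentation_result")
  res$status <- classify_status(res, fill_threshold = fill_threshold,
                                truth = truth)
  res
}

#' Classify a segmentation as full, partial or none
#'
#' With synthetic ground truth the criterion is the intersection-over-union
#' between the detected ER disk and the true embryo disk: full at IoU >= 0.9,
#' partial in \[0.3, 0.9), none below. Without ground truth, the fraction of
#' above-background pixels inside ER (background = median intensity outside
#' ER) must reach `fill_threshold` for a full segmentation.
#'
#' @param seg a `segmentation_result`.
#' @param fill_threshold above-background fill fraction for "full" on real
#'   images (default 0.8).
#' @param truth optional true circle (`center_row`, `center_col`, `radius`).
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
classify_status <- function(seg, fill_threshold = 0.8, truth = NULL) {
  if (is.null(seg$circle)) return("none")
  if (!is.null(truth)) {
    iou <- disk_iou(seg, truth)
    return(if (iou >= 0.9) "full" else if (iou >= 0.3) "partial" else "none")
  }
  m <- seg$image
  bg <- stats::median(m[!seg$er_mask])
  fill <- mean(m[seg$er_mask] > bg)
  if (fill >= fill_threshold) "full" else "partial"
}

# IoU between the detected ER disk and the true embryo disk, computed by
# pixel counting on the image raster.
disk_iou <- function(seg, truth) {
  nr <- nrow(seg$image); nc <- ncol(seg$image)
  det <- seg$er_mask
  tru <- disk_mask(nr, nc, truth$center_row, truth$center_col, truth$radius)
  sum(det & tru) / sum(det | tru)
}

#' One-line delimited export of a circle detection
#'
#' @param circle a `circle_detection`.
#' @return a single-row data.frame (center_row, center_col, radius, strength,
#'   stage).
#' @export
circle_record <- function(circle) {
  data.frame(center_row = circle$center_row, center_col = circle$center_col,
             radius = circle$radius, strength = circle$strength,
             stage = circle$stage)
}
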