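# The 36-variable feature schema and its extraction.
#
# Per region (ER, RR, TE): five angle-averaged GLCM statistics + mean
# intensity + intensity standard deviation + above-background area fraction
# (3 x 8 = 24), plus 12 whole-embryo/shape variables. The schema is frozen
# here, in one registry, so it can be swapped without touching other modules.

region_feature_names <- function(region) {
  paste0(region, "_", c("contrast", "correlation", "energy", "homogeneity",
                        "entropy", "mean", "sd", "fg_frac"))
}

#' The fixed, ordered 36-feature schema
#'
#' @return character vector of 36 feature names.
#' @export
feature_schema <- function() {
  c(region_feature_names("er"), region_feature_names("rr"),
    region_feature_names("te"),
    "er_radius", "rr_radius", "er_area", "te_area",
    "er_rr_mean_ratio", "te_rr_mean_ratio", "circle_strength",
    "grad_energy_er", "border_contrast", "centroid_offset",
    "eccentricity", "er_hist_entropy")
}

region_features <- function(img, mask, bg) {
  vals <- img[mask]
  st <- glcm_region_stats(img, mask)
  c(st,
    mean = mean(vals),
    sd = stats::sd(vals),
    fg_frac = mean(vals > bg))
}

# Shannon entropy (bits) of an 8-bin intensity histogram over [0, 255].
hist_entropy <- function(vals) {
  p <- tabulate(pmin(floor(vals / 32), 7) + 1, nbins = 8)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the 36-variable feature vector from a segmentation
#'
#' Computes, for each of the ER, RR and TE regions, the five angle-averaged
#' GLCM statistics (distance 1, 8 levels), the mean and standard deviation of
#' intensity and the above-background area fraction, plus 12 whole-embryo
#' shape/intensity variables (radii, areas, inter-region intensity ratios,
#' detection strength, gradient energy, border contrast, above-background
#' centroid offset and eccentricity, and the ER histogram entropy).
#'
#' @param seg a `segmentation_result` with status `"full"` or `"partial"`.
#' @return named numeric vector of length 36 following [feature_schema()].
#' @export
extract_features <- function(seg) {
  if (is.null(seg$circle) || identical(seg$status, "none"))
    stop("cannot extract features from an unsegmented image")
  m <- seg$image
  bg <- stats::median(m[!seg$er_mask])

  er <- region_features(m, seg$er_mask, bg)
  rr <- region_features(m, seg$rr_mask, bg)
  te <- region_features(m, seg$te_mask, bg)

  grad <- gradient_magnitude(m)
  fg <- seg$er_mask & (m > bg)
  n_fg <- sum(fg)
  cr <- seg$circle$center_row; cc <- seg$circle$center_col
  if (n_fg > 1) {
    rows <- row(m)[fg]; cols <- col(m)[fg]
    centroid_offset <- sqrt((mean(rows) - cr)^2 + (mean(cols) - cc)^2) /
      seg$er_radius
    # eccentricity proxy from second moments of the above-background mass
    vr <- stats::var(rows); vc <- stats::var(cols)
    cv <- stats::cov(rows, cols)
    tr <- vr + vc
    det_ <- vr * vc - cv^2
    disc <- sqrt(max(tr^2 / 4 - det_, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    eccentricity <- if (l1 <= 1e-12) 0 else sqrt(max(1 - l2 / l1, 0))
  } else {
    centroid_offset <- 0; eccentricity <- 0
  }
  # mean intensity just inside vs just outside the ER boundary
  ring_in <- disk_mask(nrow(m), ncol(m), cr, cc, seg$er_radius) &
    !disk_mask(nrow(m), ncol(m), cr, cc, max(seg$er_radius - 6, 1))
  ring_out <- disk_mask(nrow(m), ncol(m), cr, cc, seg$er_radius + 6) &
    !disk_mask(nrow(m), ncol(m), cr, cc, seg$er_radius)
  border_contrast <- mean(m[ring_in]) - if (sum(ring_out) > 0)
    mean(m[ring_out]) else bg

  global <- c(
    er_radius = seg$er_radius,
    rr_radius = seg$rr_radius,
    er_area = sum(seg$er_mask),
    te_area = sum(seg$te_mask),
    er_rr_mean_ratio = unname(er["mean"] / max(rr["mean"], 1e-9)),
    te_rr_mean_ratio = unname(te["mean"] / max(rr["mean"], 1e-9)),
    circle_strength = seg$circle$strength,
    grad_energy_er = mean(grad[seg$er_mask]^2),
    border_contrast = border_contrast,
    centroid_offset = centroid_offset,
    eccentricity = eccentricity,
    er_hist_entropy = hist_entropy(m[seg$er_mask])
  )
  out <- c(stats::setNames(er, region_feature_names("er")),
           stats::setNames(rr, region_feature_names("rr")),
           stats::setNames(te, region_feature_names("te")),
           global)
  stopifnot(identical(names(out), feature_schema()))
  out
}

#' Extract features for several segmentations into a table
#'
#' @param segs list of `segmentation_result` objects.
#' @return data.frame with one row per segmentation, columns per
#'   [feature_schema()].
#' @export
feature_table <- function(segs) {
  as.data.frame(do.call(rbind, lapply(segs, extract_features)))
}
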