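# Ground-truthed synthetic blastocyst images and feature datasets.
#
# The renderer emulates the two capture regimes: "microscope" (embryo around
# a quarter of the frame) and two smartphone regimes calibrated from the
# occupancy measurements of the study images — Dataset-1-like (about 3% of
# the frame area, radius 45-75 px at 640x480) and Dataset-2-like (about
# 0.24%, radius 10-20 px). Smartphone regimes render at 1280x960 and
# downsample by two, emulating optical capture through an ocular.
#
# Anatomy rendered: a bright zona-pellucida ring at the true radius, a
# textured trophectoderm annulus (thickness 40 px scaled by radius/150), a
# darker blastocoel, and an off-center inner-cell-mass blob. Grade controls
# degradation: grade 1 clean and symmetric; grade 2 with 15% ring erasure
# and moderate shape noise; grade 3 with 35% erasure, strong asymmetry and
# vacuole speckles.

REGIME_RADIUS_RANGES <- list(microscope = c(100, 200),
                             smartphone_d1 = c(45, 75),
                             smartphone_d2 = c(10, 20))

#' Specification for one synthetic blastocyst image
#'
#' @param regime `"microscope"`, `"smartphone_d1"` or `"smartphone_d2"`.
#' @param radius true embryo radius in final-frame pixels; `NULL` draws
#'   uniformly from the regime's default range.
#' @param grade IETS-style quality grade 1 (excellent/good), 2 (fair) or
#'   3 (poor).
#' @param noise_sd Gaussian pixel noise standard deviation (default 5).
#' @param background `"flat"` or `"gradient"`.
#' @param center optional (row, col) of the true center; `NULL` places the
#'   embryo near frame center with a small random offset.
#' @param seed RNG seed; rendering is deterministic per spec + seed.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(regime = c("microscope", "smartphone_d1",
                                      "smartphone_d2"),
                           radius = NULL, grade = 1L, noise_sd = 5,
                           background = c("flat", "gradient"),
                           center = NULL, seed = 1L) {
  regime <- match.arg(regime)
  background <- match.arg(background)
  stopifnot(grade %in% 1:3, noise_sd >= 0)
  structure(list(regime = regime, radius = radius, grade = as.integer(grade),
                 noise_sd = noise_sd, background = background,
                 center = center, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Smooth pseudo-texture: white noise box-blurred twice.
smooth_noise <- function(nr, nc, sd) {
  z <- matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  for (pass in 1:2) {
    z <- (z + shift_mat(z, 1, 0) + shift_mat(z, -1, 0) +
            shift_mat(z, 0, 1) + shift_mat(z, 0, -1)) / 5
  }
  z
}

#' Render a synthetic blastocyst image with ground truth
#'
#' @param spec a `synthetic_spec`.
#' @return list with `image` (a `raw_image`, 640x480 grayscale) and `truth`
#'   (list: `center_row`, `center_col`, `radius`, `grade`, plus the true
#'   ER/RR/TE masks at the pipeline's +5/-40 offsets when they exist).
#' @export
render_blastocyst <- function(spec) {
  set.seed(spec$seed)
  hi_res <- spec$regime != "microscope"
  f <- if (hi_res) 2L else 1L            # supersampling factor
  nr <- 480L * f; nc <- 640L * f
  rng <- REGIME_RADIUS_RANGES[[spec$regime]]
  radius <- if (is.null(spec$radius))
    stats::runif(1, rng[1], rng[2]) else spec$radius
  if (radius * 2 > min(480, 640) * 0.95)
    stop("geometry error: radius ", radius, " too large for the frame")
  r <- radius * f
  if (is.null(spec$center)) {
    margin <- r + 20 * f
    cr <- stats::runif(1, margin, nr - margin)
    cc <- stats::runif(1, margin, nc - margin)
  } else {
    cr <- spec$center[1] * f; cc <- spec$center[2] * f
  }

  bg_level <- 40
  m <- matrix(bg_level, nr, nc)
  if (spec$background == "gradient")
    m <- m + outer(seq(-12, 12, length.out = nr), rep(1, nc))
  m <- m + smooth_noise(nr, nc, 4)

  d <- sqrt(dist2_from(nr, nc, cr, cc))
  theta <- atan2(row(m) - cr, col(m) - cc)

  # grade-dependent degradation
  wobble_amp <- c(0, 0.02, 0.05)[spec$grade]
  erase_frac <- c(0, 0.15, 0.35)[spec$grade]
  phase <- stats::runif(1, 0, 2 * pi)
  r_eff <- r * (1 + wobble_amp * sin(3 * theta + phase))

  # thicknesses defined at the reference radius 150 in final-frame pixels
  # (zona 4 px, trophectoderm 40 px), scaled by radius/150, in supersampled
  # units
  radius_final <- r / f
  zona_w <- max(2, 4 * radius_final / 150) * f
  te_w <- max(4, 40 * radius_final / 150) * f

  inside <- d <= r_eff
  zona <- d <= r_eff & d > (r_eff - zona_w)
  te_band <- d <= (r_eff - zona_w) & d > (r_eff - zona_w - te_w)
  cavity <- d <= (r_eff - zona_w - te_w)

  m[cavity] <- 95
  te_tex <- smooth_noise(nr, nc, 14 - 3 * spec$grade)
  m[te_band] <- 135 + te_tex[te_band]
  contrast_drop <- c(0, 15, 30)[spec$grade]
  m[zona] <- 215 - contrast_drop

  # inner cell mass: off-center blob inside the cavity
  icm_off <- (0.35 + 0.1 * (spec$grade - 1)) * r
  icm_dir <- stats::runif(1, 0, 2 * pi)
  icm_r <- 0.28 * r
  icm <- dist2_from(nr, nc, cr + icm_off * sin(icm_dir),
                    cc + icm_off * cos(icm_dir)) <= icm_r^2
  icm <- icm & cavity
  m[icm] <- 160 + te_tex[icm]

  # ring erasure: contiguous arcs knocked back to background
  if (erase_frac > 0) {
    n_arcs <- spec$grade
    arc_len <- 2 * pi * erase_frac / n_arcs
    for (a in seq_len(n_arcs)) {
      a0 <- stats::runif(1, -pi, pi)
      dth <- (theta - a0 + pi) %% (2 * pi) - pi
      hit <- zona & abs(dth) < arc_len / 2
      m[hit] <- bg_level + te_tex[hit]
    }
  }

  # vacuole speckles for grade 3
  if (spec$grade == 3) {
    for (v in 1:12) {
      vr <- stats::runif(1, 0.03, 0.08) * r
      vd <- stats::runif(1, 0.2, 0.8) * r
      va <- stats::runif(1, 0, 2 * pi)
      vac <- dist2_from(nr, nc, cr + vd * sin(va), cc + vd * cos(va)) <= vr^2
      vac <- vac & inside
      m[vac] <- 70
    }
  }

  m <- m + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  m <- pmin(pmax(m, 0), 255)
  if (hi_res) m <- resample_image(m, 480L, 640L, "bilinear")
  img <- new_raw_image(round(m), "synthetic", "in-memory")
  img$source_tag <- if (hi_res) "smartphone" else "microscope"

  truth <- list(center_row = cr / f, center_col = cc / f, radius = radius,
                grade = spec$grade)
  if (radius - RR_SHRINK_PX > 0) {
    truth$er_mask <- disk_mask(480L, 640L, truth$center_row,
                               truth$center_col, radius + ER_GROW_PX)
    truth$rr_mask <- disk_mask(480L, 640L, truth$center_row,
                               truth$center_col, radius - RR_SHRINK_PX)
    truth$te_mask <- truth$er_mask & !truth$rr_mask
  }
  list(image = img, truth = truth)
}

#' Occupancy of an embryo circle in its frame
#'
#' area_fraction = pi r^2 / (H W); interception_fraction = 2 r / W (diameter
#' over the maximum frame width) — the two measurements used to calibrate
#' the capture regimes.
#'
#' @param circle list with `radius` (ground truth or a detection).
#' @param dim frame (rows, cols), default 480 x 640.
#' @return list with `area_fraction` and `interception_fraction`.
#' @export
measure_occupancy <- function(circle, dim = c(480L, 640L)) {
  if (is.null(circle) || is.null(circle$radius))
    stop("no circle available for occupancy measurement")
  r <- circle$radius
  list(area_fraction = pi * r^2 / prod(dim),
       interception_fraction = 2 * r / dim[2])
}

#' Generate a labeled synthetic feature dataset
#'
#' Three 24-dimensional Gaussian clusters whose class means are `separation`
#' (in within-class SD units) apart pairwise, with correlated blocks in the
#' within-class covariance. A surrogate for training/grading experiments
#' when no feature table from real images is at hand.
#'
#' @param n_per_class samples per grade class (>= 5).
#' @param separation pairwise Euclidean distance between class means, in SD
#'   units (default 6: nearly disjoint clusters).
#' @param seed RNG seed.
#' @param n_features feature dimension (default 24).
#' @return list with `features` (matrix, columns `f01`...) and `labels`
#'   (integer grades 1..3).
#' @export
generate_feature_dataset <- function(n_per_class = 100L, separation = 6,
                                     seed = 1L, n_features = 24L) {
  stopifnot(n_per_class >= 5)
  set.seed(seed)
  # class means: simplex in the first 3 coordinates, pairwise distance
  # = separation (unit within-class SD)
  s <- separation / sqrt(2)
  means <- rbind(c(s, 0, 0), c(0, s, 0), c(0, 0, s))
  # block-correlated within-class covariance (blocks of 4, rho = 0.3)
  block <- matrix(0.3, 4, 4); diag(block) <- 1
  L_blk <- chol(block)
  n <- 3L * n_per_class
  X <- matrix(0, n, n_features)
  for (b in seq_len(n_features %/% 4)) {
    cols <- (b - 1) * 4 + 1:4
    X[, cols] <- matrix(stats::rnorm(n * 4), n, 4) %*% L_blk
  }
  rem <- n_features %% 4
  if (rem > 0)
    X[, n_features - rem + seq_len(rem)] <-
      matrix(stats::rnorm(n * rem), n, rem)
  labels <- rep(1:3, each = n_per_class)
  X[, 1:3] <- X[, 1:3] + means[labels, ]
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  list(features = X, labels = labels)
}

#' Append constructed collinear columns to a feature matrix
#'
#' Adds `n_extra` columns, each the mean of a disjoint pair of original
#' columns plus small Gaussian noise. Each appended column is algebraically
#' guaranteed a larger VIF than its parents, so greedy max-VIF pruning
#' removes exactly the appended set — mirroring a 36 -> 24 reduction when 12
#' columns are appended to 24.
#'
#' @param features N x K matrix (K >= 2 * n_extra).
#' @param n_extra number of appended columns (default 12).
#' @param noise_sd perturbation SD (default 0.02).
#' @param seed RNG seed.
#' @return matrix with `K + n_extra` columns; appended columns are named
#'   `dup01`...
#' @export
extend_with_collinear <- function(features, n_extra = 12L, noise_sd = 0.02,
                                  seed = 1L) {
  stopifnot(ncol(features) >= 2 * n_extra)
  # decouple this RNG stream from the one that generated `features`, so the
  # perturbation can never replay (and thus be collinear with) the draws
  # that built the original columns
  set.seed((seed * 48271 + 1664525) %% 2147483647)
  extra <- sapply(seq_len(n_extra), function(k) {
    a <- features[, 2 * k - 1]; b <- features[, 2 * k]
    (a + b) / 2 + stats::rnorm(nrow(features), 0, noise_sd)
  })
  colnames(extra) <- sprintf("dup%02d", seq_len(n_extra))
  cbind(features, extra)
}

#' Write a directory of synthetic fixture images with a manifest
#'
#' @param dir output directory (created if needed).
#' @param specs list of `synthetic_spec` objects.
#' @return data.frame manifest (path, regime, grade, center_row, center_col,
#'   radius, seed), also written to `manifest.csv` in `dir`.
#' @export
write_synthetic_fixtures <- function(dir, specs) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(specs), function(i) {
    rendered <- render_blastocyst(specs[[i]])
    path <- file.path(dir, sprintf("synthetic_%03d.png", i))
    write_image_png(rendered$image$pixels, path)
    data.frame(path = path, regime = specs[[i]]$regime,
               grade = rendered$truth$grade,
               center_row = rendered$truth$center_row,
               center_col = rendered$truth$center_col,
               radius = rendered$truth$radius, seed = specs[[i]]$seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
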