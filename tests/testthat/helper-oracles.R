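# Independent oracles used across the suite. These re-derive expected values
# by brute force or closed form and must stay independent of the package's
# own implementation paths.

# All-pairs GLCM enumeration: loop over every pixel pair at the offset.
brute_glcm <- function(img, mask, distance, angle, levels) {
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  lev <- pmin(pmax(floor(img / (256 / levels)), 0), levels - 1)
  g <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
    if (!mask[r, c] || !mask[r2, c2]) next
    a <- lev[r, c] + 1; b <- lev[r2, c2] + 1
    g[a, b] <- g[a, b] + 1
    g[b, a] <- g[b, a] + 1
  }
  g
}

# VIF from the explicit normal equations of the auxiliary regression.
vif_normal_equations <- function(X, k) {
  y <- X[, k]
  Z <- cbind(1, X[, -k, drop = FALSE])
  beta <- solve(t(Z) %*% Z, t(Z) %*% y)
  resid <- y - Z %*% beta
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  1 / (1 - r2)
}

# VIF from the diagonal of the inverse correlation matrix.
vif_inverse_correlation <- function(X, k) {
  diag(solve(stats::cor(X)))[k]
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration (sum of point probabilities <= observed).
fisher_enum_2x2 <- function(t) {
  t <- as.matrix(t)
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(t[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive loop-based forward pass for a trained network (no matrix algebra).
naive_forward <- function(ann, x) {
  tfs <- c(ann$architecture$tf_hidden[seq_len(ann$architecture$n_hidden_layers)],
           ann$architecture$tf_output)
  a <- (x - ann$x_mu) / ann$x_sd
  for (l in seq_along(ann$layers)) {
    W <- ann$layers[[l]]$W; b <- ann$layers[[l]]$b
    z <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      s <- b[j]
      for (i in seq_len(nrow(W))) s <- s + a[i] * W[i, j]
      z[j] <- s
    }
    a <- switch(tfs[l],
                logistic_sigmoid = 1 / (1 + exp(-z)),
                tanh_sigmoid = tanh(z),
                linear = z)
  }
  e <- exp(a - max(a))
  e / sum(e)
}

# Render-and-segment helper for microscope-regime ground-truth images.
segment_synthetic <- function(radius, grade = 1, seed = 1,
                              regime = "microscope") {
  rb <- render_blastocyst(synthetic_spec(regime, radius = radius,
                                         grade = grade, seed = seed))
  std <- standardize(rb$image)
  binary <- binarize(gradient_magnitude(std))
  det <- two_stage_detect(binary)
  list(rendered = rb, std = std, binary = binary, detection = det)
}

# Rasterized circle ring (edge pixels only) for Hough tests.
draw_ring <- function(nr, nc, cr, cc, r, thickness = 1) {
  d <- sqrt(outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`))
  abs(d - r) <= thickness / 2 + 0.5
}

# Small trained ensemble on a separable synthetic feature dataset.
make_test_ensemble <- function(seed = 5, n_per_class = 60) {
  ds <- generate_feature_dataset(n_per_class, separation = 6, seed = seed)
  spl <- split_dataset(ds$features, ds$labels, seed = seed)
  archs <- list(
    architecture(n_hidden = c(10, 8, 8), train_fn = "rprop"),
    architecture(n_hidden = c(8, 8, 8), tf_hidden = rep("tanh_sigmoid", 3),
                 train_fn = "rprop", n_hidden_layers = 2),
    architecture(n_hidden = c(12, 8, 8), train_fn = "gradient_descent_momentum"))
  list(dataset = ds, split = spl,
       models = train_ensemble(spl, archs, seed = seed, max_epochs = 120))
}

# Inclusive-boundary disk mask (duplicated small utility for tests).
disk_mask_for_test <- function(nr, nc, cr, cc, r) {
  outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`) <= r^2
}
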