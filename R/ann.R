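# Feedforward networks trained by backpropagation.
#
# An architecture is a 9-gene chromosome: neuron counts for up to three
# hidden layers, a transfer function per hidden layer, the output transfer
# function, the training algorithm, and the number of active hidden layers
# (genes beyond the active depth are carried but inert — exactly how the
# genetic search treats them).

TRANSFER_FUNCTIONS <- c("logistic_sigmoid", "tanh_sigmoid", "linear")
TRAINING_FUNCTIONS <- c("gradient_descent", "gradient_descent_momentum",
                        "rprop")
MAX_NEURONS <- 64L

#' Construct (and validate) an ANN architecture
#'
#' @param n_hidden integer vector of length 3, neurons per hidden layer
#'   (each in 1..64).
#' @param tf_hidden character vector of length 3, transfer function per
#'   hidden layer.
#' @param tf_output output-layer transfer function.
#' @param train_fn training algorithm.
#' @param n_hidden_layers active depth, 1..3.
#' @return an `ann_architecture`.
#' @export
architecture <- function(n_hidden = c(8L, 8L, 8L),
                         tf_hidden = rep("logistic_sigmoid", 3),
                         tf_output = "linear",
                         train_fn = "rprop",
                         n_hidden_layers = 1L) {
  stopifnot(length(n_hidden) == 3, all(n_hidden >= 1), all(n_hidden <= MAX_NEURONS),
            length(tf_hidden) == 3, all(tf_hidden %in% TRANSFER_FUNCTIONS),
            tf_output %in% TRANSFER_FUNCTIONS,
            train_fn %in% TRAINING_FUNCTIONS,
            n_hidden_layers %in% 1:3)
  structure(list(n_hidden = as.integer(n_hidden), tf_hidden = tf_hidden,
                 tf_output = tf_output, train_fn = train_fn,
                 n_hidden_layers = as.integer(n_hidden_layers)),
            class = "ann_architecture")
}

#' @export
print.ann_architecture <- function(x, ...) {
  d <- x$n_hidden_layers
  cat("<architecture>", paste(x$n_hidden[seq_len(d)], collapse = "-"),
      "neurons |", paste(x$tf_hidden[seq_len(d)], collapse = ","),
      "| out:", x$tf_output, "| train:", x$train_fn, "\n")
  invisible(x)
}

# The 9 genes as a flat named vector (integer codes for the enums).
architecture_genes <- function(arch) {
  c(h1 = arch$n_hidden[1], h2 = arch$n_hidden[2], h3 = arch$n_hidden[3],
    tf1 = match(arch$tf_hidden[1], TRANSFER_FUNCTIONS),
    tf2 = match(arch$tf_hidden[2], TRANSFER_FUNCTIONS),
    tf3 = match(arch$tf_hidden[3], TRANSFER_FUNCTIONS),
    tfo = match(arch$tf_output, TRANSFER_FUNCTIONS),
    trf = match(arch$train_fn, TRAINING_FUNCTIONS),
    depth = arch$n_hidden_layers)
}

genes_to_architecture <- function(g) {
  architecture(n_hidden = g[1:3],
               tf_hidden = TRANSFER_FUNCTIONS[g[4:6]],
               tf_output = TRANSFER_FUNCTIONS[g[7]],
               train_fn = TRAINING_FUNCTIONS[g[8]],
               n_hidden_layers = g[9])
}

transfer <- function(z, name) {
  switch(name,
         logistic_sigmoid = 1 / (1 + exp(-z)),
         tanh_sigmoid = tanh(z),
         linear = z)
}

transfer_deriv <- function(a, name) {  # derivative in terms of activation a
  switch(name,
         logistic_sigmoid = a * (1 - a),
         tanh_sigmoid = 1 - a^2,
         linear = array(1, dim(a)))
}

# Layer sizes input -> hidden(s) -> output for 24 -> ... -> 3.
layer_sizes <- function(arch, n_in = 24L, n_out = 3L) {
  c(n_in, arch$n_hidden[seq_len(arch$n_hidden_layers)], n_out)
}

init_weights <- function(arch, n_in, n_out, seed) {
  set.seed(seed)
  sizes <- layer_sizes(arch, n_in, n_out)
  lapply(seq_len(length(sizes) - 1), function(l) {
    list(W = matrix(stats::runif(sizes[l] * sizes[l + 1], -0.1, 0.1),
                    sizes[l], sizes[l + 1]),
         b = stats::runif(sizes[l + 1], -0.1, 0.1))
  })
}

layer_tfs <- function(arch) {
  c(arch$tf_hidden[seq_len(arch$n_hidden_layers)], arch$tf_output)
}

# Forward pass; X is N x n_in. Returns list(activations, scores).
ann_forward <- function(layers, tfs, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(X), length(layers[[l]]$b), byrow = TRUE)
    acts[[l + 1]] <- transfer(z, tfs[l])
  }
  y <- acts[[length(acts)]]
  # normalization to class scores summing to 1 (softmax over the output
  # activations; monotone, so argmax is unchanged)
  e <- exp(y - apply(y, 1, max))
  scores <- e / rowSums(e)
  list(acts = acts, scores = scores)
}

ce_loss <- function(scores, onehot) {
  -mean(rowSums(onehot * log(pmax(scores, 1e-12))))
}

# Backpropagated gradients of the cross-entropy loss.
ann_gradients <- function(layers, tfs, acts, scores, onehot) {
  n <- nrow(onehot)
  L <- length(layers)
  grads <- vector("list", L)
  # d loss / d output-activation through softmax is (scores - onehot)/n;
  # then through the output transfer function.
  delta <- (scores - onehot) / n
  delta <- delta * transfer_deriv(acts[[L + 1]], tfs[L])
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1)
      delta <- (delta %*% t(layers[[l]]$W)) *
        transfer_deriv(acts[[l]], tfs[l - 1])
  }
  grads
}

# One full-batch parameter update; state carries momentum / rprop memory.
ann_update <- function(layers, grads, train_fn, state, lr = 0.5) {
  if (train_fn == "gradient_descent") {
    for (l in seq_along(layers)) {
      layers[[l]]$W <- layers[[l]]$W - lr * grads[[l]]$W
      layers[[l]]$b <- layers[[l]]$b - lr * grads[[l]]$b
    }
  } else if (train_fn == "gradient_descent_momentum") {
    mom <- 0.9
    if (is.null(state$vel))
      state$vel <- lapply(layers, function(l)
        list(W = l$W * 0, b = l$b * 0))
    for (l in seq_along(layers)) {
      state$vel[[l]]$W <- mom * state$vel[[l]]$W - lr * grads[[l]]$W
      state$vel[[l]]$b <- mom * state$vel[[l]]$b - lr * grads[[l]]$b
      layers[[l]]$W <- layers[[l]]$W + state$vel[[l]]$W
      layers[[l]]$b <- layers[[l]]$b + state$vel[[l]]$b
    }
  } else {  # rprop (Rprop-): sign-based per-weight step adaptation
    eta_p <- 1.2; eta_m <- 0.5; d_max <- 50; d_min <- 1e-6
    if (is.null(state$step)) {
      state$step <- lapply(layers, function(l)
        list(W = l$W * 0 + 0.1, b = l$b * 0 + 0.1))
      state$gprev <- lapply(layers, function(l)
        list(W = l$W * 0, b = l$b * 0))
    }
    for (l in seq_along(layers)) {
      for (part in c("W", "b")) {
        g <- grads[[l]][[part]]
        sgn <- sign(g * state$gprev[[l]][[part]])
        st <- state$step[[l]][[part]]
        st[sgn > 0] <- pmin(st[sgn > 0] * eta_p, d_max)
        st[sgn < 0] <- pmax(st[sgn < 0] * eta_m, d_min)
        state$step[[l]][[part]] <- st
        g[sgn < 0] <- 0  # do not step over a sign change
        layers[[l]][[part]] <- layers[[l]][[part]] - sign(g) * st
        state$gprev[[l]][[part]] <- g
      }
    }
  }
  list(layers = layers, state = state)
}

onehot_encode <- function(labels, n_class = 3) {
  y <- matrix(0, length(labels), n_class)
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}

#' Train a feedforward network by backpropagation
#'
#' Full-batch training of the architecture's network on z-scored inputs
#' (standardization statistics come from the training split and are stored
#' with the model), minimizing cross-entropy on one-hot three-class targets,
#' with early stopping on the validation loss.
#'
#' @param train,validation lists with `x` (matrix, 24 columns) and `y`
#'   (grades 1..3), as produced by [split_dataset()].
#' @param arch an `ann_architecture`.
#' @param seed RNG seed for weight initialization.
#' @param max_epochs epoch budget (default 200). A zero budget returns the
#'   initialized network with an empty log.
#' @param patience epochs without validation improvement before stopping
#'   (default 25).
#' @param learning_rate step size for the gradient-descent training
#'   functions (ignored by rprop).
#' @return a `trained_ann`: layers, architecture, normalization stats, input
#'   schema, class labels and the per-epoch training log.
#' @export
train_ann <- function(train, validation, arch, seed = 1L, max_epochs = 200L,
                      patience = 25L, learning_rate = 0.5) {
  x_mu <- colMeans(train$x)
  x_sd <- apply(train$x, 2, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  zx <- function(x) sweep(sweep(x, 2, x_mu), 2, x_sd, "/")
  Xtr <- zx(train$x); Xva <- zx(validation$x)
  Ytr <- onehot_encode(train$y); Yva <- onehot_encode(validation$y)

  layers <- init_weights(arch, ncol(Xtr), 3L, seed)
  tfs <- layer_tfs(arch)
  state <- new.env(parent = emptyenv())
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- list(layers = layers, val = Inf, since = 0L)

  for (epoch in seq_len(max_epochs)) {
    fw <- ann_forward(layers, tfs, Xtr)
    tr_loss <- ce_loss(fw$scores, Ytr)
    if (!is.finite(tr_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    grads <- ann_gradients(layers, tfs, fw$acts, fw$scores, Ytr)
    upd <- ann_update(layers, grads, arch$train_fn, state, lr = learning_rate)
    layers <- upd$layers; state <- upd$state
    va_loss <- ce_loss(ann_forward(layers, tfs, Xva)$scores, Yva)
    if (!is.finite(va_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                 val_loss = va_loss))
    if (va_loss < best$val - 1e-9) {
      best <- list(layers = layers, val = va_loss, since = 0L)
    } else {
      best$since <- best$since + 1L
      if (best$since >= patience) break
    }
  }
  structure(list(architecture = arch,
                 layers = if (max_epochs > 0) best$layers else layers,
                 x_mu = x_mu, x_sd = x_sd,
                 input_schema = colnames(train$x),
                 class_labels = c("1" = "excellent_good", "2" = "fair",
                                  "3" = "poor"),
                 training_log = log, rng_seed = seed),
            class = "trained_ann")
}

#' @export
print.trained_ann <- function(x, ...) {
  cat("<trained_ann>", length(x$layers) - 1, "hidden layer(s),",
      nrow(x$training_log), "epochs, final val loss",
      if (nrow(x$training_log)) sprintf("%.4f", min(x$training_log$val_loss))
      else "NA", "\n")
  invisible(x)
}

#' Predict a grade from a reduced feature vector
#'
#' Forward pass through a trained network; the grade is the argmax of the
#' class scores, with exact ties broken toward the worse (higher-numbered)
#' grade.
#'
#' @param ann a `trained_ann`.
#' @param x numeric vector (or 1-row matrix) matching `ann$input_schema`.
#' @return list with `grade` (1, 2 or 3) and `scores` (length-3, sums to 1).
#' @export
predict_grade <- function(ann, x) {
  x <- as_feature_row(ann, x)
  xz <- sweep(sweep(x, 2, ann$x_mu), 2, ann$x_sd, "/")
  scores <- ann_forward(ann$layers, layer_tfs(ann$architecture), xz)$scores[1, ]
  grade <- max(which(scores == max(scores)))  # tie -> worse grade
  list(grade = grade, scores = scores)
}

as_feature_row <- function(ann, x) {
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  if (ncol(x) != length(ann$x_mu))
    stop("input has ", ncol(x), " features; the model expects ",
         length(ann$x_mu))
  if (!is.null(colnames(x)) && !is.null(ann$input_schema) &&
      !identical(colnames(x), ann$input_schema)) {
    if (!all(ann$input_schema %in% colnames(x)))
      stop("input features do not match the model's input schema")
    x <- x[, ann$input_schema, drop = FALSE]
  }
  x
}

#' Save / load a trained network as versioned JSON
#'
#' @param ann a `trained_ann`.
#' @param path file path.
#' @return `path` (save) or the restored `trained_ann` (load).
#' @export
save_ann <- function(ann, path) {
  obj <- list(format = "blastograde-ann", version = 1L,
              genes = as.list(architecture_genes(ann$architecture)),
              x_mu = ann$x_mu, x_sd = ann$x_sd,
              input_schema = ann$input_schema,
              rng_seed = ann$rng_seed,
              layers = stats::setNames(
                lapply(ann$layers, function(l) list(W = l$W, b = l$b)),
                paste0("layer", seq_along(ann$layers))))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_ann
#' @export
load_ann <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(obj$format, "blastograde-ann"))
    stop("not a blastograde ANN container: ", path)
  arch <- genes_to_architecture(unlist(obj$genes))
  layers <- lapply(obj$layers, function(l) {
    W <- l$W
    if (!is.matrix(W)) W <- matrix(unlist(W), ncol = length(l$b))
    list(W = W, b = as.numeric(l$b))
  })
  structure(list(architecture = arch, layers = layers,
                 x_mu = stats::setNames(unlist(obj$x_mu), obj$input_schema),
                 x_sd = stats::setNames(unlist(obj$x_sd), obj$input_schema),
                 input_schema = obj$input_schema,
                 class_labels = c("1" = "excellent_good", "2" = "fair",
                                  "3" = "poor"),
                 training_log = data.frame(), rng_seed = obj$rng_seed),
            class = "trained_ann")
}
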