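#' Layer geometry of the engram classifier
#'
#' Describes the fixed architecture used throughout: two valid (no-padding)
#' convolution layers, each optionally followed by 2x2 stride-2 max pooling,
#' then global max pooling to a per-channel latent vector, a fully connected
#' hidden layer (the engram layer targeted by dropout), and a linear output
#' head.  For the default geometry a 28x28x1 input maps through
#' 26x26x32 -> 13x13x32 -> 11x11x64 -> 5x5x64 -> 64 -> 100 -> `n_classes`.
#'
#' When a pooled spatial dimension is odd, the trailing row/column is dropped
#' (floor division), which is what takes the 11x11 conv2 output to 5x5.
#'
#' @param input_size spatial side length of the (square, single-channel)
#'   input images.
#' @param kernel convolution kernel side length, shared by both layers.
#' @param filters integer vector of length 2: filter counts of the two
#'   convolution layers.  The second count is also the latent dimension.
#' @param pool logical; apply 2x2 max pooling after each convolution.
#' @param fc_units width of the fully connected hidden (engram) layer.
#' @return An object of class `"layer_shapes"`: a list of the geometry plus
#'   the derived feature-map sizes.
#' @examples
#' layer_shapes()          # the standard geometry
#' layer_shapes(input_size = 6, kernel = 2, filters = c(2, 2), fc_units = 5)
#' @export
layer_shapes <- function(input_size = 28L, kernel = 3L, filters = c(32L, 64L),
                         pool = TRUE, fc_units = 100L) {
  input_size <- check_count(input_size, "input_size", min = 1L)
  kernel <- check_count(kernel, "kernel", min = 1L)
  if (length(filters) != 2L) stop_bad("'filters' must have length 2")
  f1 <- check_count(filters[1L], "filters[1]")
  f2 <- check_count(filters[2L], "filters[2]")
  fc_units <- check_count(fc_units, "fc_units")
  if (kernel > input_size)
    stop_bad("kernel (%d) larger than input (%d)", kernel, input_size)

  o1 <- input_size - kernel + 1L
  if (pool && o1 < 2L)
    stop_bad("conv1 output %dx%d too small for 2x2 pooling", o1, o1)
  p1 <- if (pool) o1 %/% 2L else o1
  if (kernel > p1)
    stop_bad("conv2 kernel (%d) larger than its %dx%d input", kernel, p1, p1)
  o2 <- p1 - kernel + 1L
  if (pool && o2 < 2L)
    stop_bad("conv2 output %dx%d too small for 2x2 pooling", o2, o2)
  p2 <- if (pool) o2 %/% 2L else o2

  structure(list(
    input_rows = input_size, input_cols = input_size,
    kernel1 = kernel, filters1 = f1, kernel2 = kernel, filters2 = f2,
    pool = isTRUE(pool), fc_units = fc_units,
    conv1_out = c(o1, o1, f1), pool1_out = c(p1, p1, f1),
    conv2_out = c(o2, o2, f2), pool2_out = c(p2, p2, f2),
    latent = f2
  ), class = "layer_shapes")
}

#' @export
print.layer_shapes <- function(x, ...) {
  cat("Engram-network geometry\n")
  cat(sprintf("  input   %dx%dx1\n", x$input_rows, x$input_cols))
  cat(sprintf("  conv1   %d filters %dx%d (valid) -> %s\n", x$filters1,
              x$kernel1, x$kernel1, paste(x$conv1_out, collapse = "x")))
  if (x$pool)
    cat(sprintf("  pool1   2x2 stride 2 -> %s\n",
                paste(x$pool1_out, collapse = "x")))
  cat(sprintf("  conv2   %d filters %dx%d (valid) -> %s\n", x$filters2,
              x$kernel2, x$kernel2, paste(x$conv2_out, collapse = "x")))
  if (x$pool)
    cat(sprintf("  pool2   2x2 stride 2 -> %s\n",
                paste(x$pool2_out, collapse = "x")))
  cat(sprintf("  global max pool -> %d latent features\n", x$latent))
  cat(sprintf("  fully connected %d units (dropout target), ReLU\n",
              x$fc_units))
  invisible(x)
}

# Internal: shapes list augmented with the class count, as the C++ engine
# expects it.
shapes_for_engine <- function(shapes, n_classes) {
  s <- unclass(shapes)
  s$n_classes <- as.integer(n_classes)
  s
}

#' Loss specification
#'
#' The networks are trained against one-hot targets with, by default,
#' independent per-class sigmoid outputs scored by the mean binary
#' cross-entropy over classes.  A softmax + categorical cross-entropy variant
#' is available for sensitivity analysis.  Predicted probabilities are
#' clipped to `[clip_epsilon, 1 - clip_epsilon]` so the loss stays finite at
#' saturated outputs.
#'
#' @param variant `"bce"` (per-class sigmoid binary cross-entropy, default)
#'   or `"softmax"` (categorical cross-entropy).
#' @param clip_epsilon probability floor in (0, 0.01].
#' @return An object of class `"loss_spec"`.
#' @export
loss_spec <- function(variant = c("bce", "softmax"), clip_epsilon = 1e-7) {
  variant <- match.arg(variant)
  if (!is.numeric(clip_epsilon) || length(clip_epsilon) != 1L ||
      clip_epsilon <= 0 || clip_epsilon > 0.01)
    stop_bad("'clip_epsilon' must be in (0, 0.01]")
  structure(list(variant = variant, clip_epsilon = as.numeric(clip_epsilon)),
            class = "loss_spec")
}

loss_code <- function(loss) if (loss$variant == "bce") 0L else 1L

#' Initialize network parameters
#'
#' Weights are drawn from a fan-in-scaled uniform distribution
#' `U(-sqrt(6 / fan_in), sqrt(6 / fan_in))`; biases start at zero.
#' Initialization is a pure function of `(shapes, n_classes, seed)`.
#'
#' @param shapes a [layer_shapes()] object.
#' @param n_classes number of output classes (>= 2).
#' @param seed integer RNG seed.
#' @return An object of class `"network_params"`: a named list of arrays
#'   `W1 (k,k,1,f1)`, `b1`, `W2 (k,k,f1,f2)`, `b2`, `Wf (latent,fc)`, `bf`,
#'   `Wo (fc,n_classes)`, `bo`, with the geometry attached as attributes.
#' @examples
#' p <- init_network(layer_shapes(), n_classes = 10, seed = 7)
#' dim(p$Wo)   # 100 x 10
#' @export
init_network <- function(shapes = layer_shapes(), n_classes, seed = 1L) {
  stopifnot(inherits(shapes, "layer_shapes"))
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  k1 <- shapes$kernel1; f1 <- shapes$filters1
  k2 <- shapes$kernel2; f2 <- shapes$filters2
  fc <- shapes$fc_units; lat <- shapes$latent

  uni <- function(n, fan_in) {
    s <- sqrt(6 / fan_in)
    stats::runif(n, -s, s)
  }
  params <- with_seed(seed, list(
    W1 = array(uni(k1 * k1 * 1 * f1, k1 * k1), dim = c(k1, k1, 1L, f1)),
    b1 = numeric(f1),
    W2 = array(uni(k2 * k2 * f1 * f2, k2 * k2 * f1), dim = c(k2, k2, f1, f2)),
    b2 = numeric(f2),
    Wf = matrix(uni(lat * fc, lat), lat, fc),
    bf = numeric(fc),
    Wo = matrix(uni(fc * n_classes, fc), fc, n_classes),
    bo = numeric(n_classes)
  ))
  structure(params, class = "network_params", shapes = shapes,
            n_classes = n_classes, init_seed = seed)
}

#' @export
print.network_params <- function(x, ...) {
  s <- attr(x, "shapes")
  cat(sprintf("network_params: %d classes, %s trainable values (seed %d)\n",
              attr(x, "n_classes"),
              format(sum(vapply(x, length, 1L)), big.mark = ","),
              attr(x, "init_seed")))
  invisible(x)
}

n_parameters <- function(params) sum(vapply(params, length, 1L))

#' Single layer operations
#'
#' Building blocks of the forward pass, exposed for inspection and testing:
#' valid (no-padding) 2-D convolution, rectified linear activation, 2x2
#' stride-2 max pooling (odd trailing row/column dropped), global max
#' pooling, and a dense affine map.  The pooling operations also return the
#' argmax positions used to route gradients in the backward pass.
#'
#' @param input numeric array `(height, width, channels)` (for `relu`, any
#'   numeric array; for `dense_forward`, a vector).
#' @param weights convolution kernels `(k, k, in_channels, out_channels)`,
#'   or for `dense_forward` a `(in, out)` matrix.
#' @param biases numeric vector, one per output channel/unit.
#' @param x numeric array.
#' @return `conv2d_forward`: the `(h-k+1, w-k+1, out_channels)` feature map.
#'   `maxpool2x2_forward` / `global_maxpool_forward`: a list with `output`
#'   and `argmax` (1-based linear index into each channel's spatial plane).
#'   `relu` and `dense_forward` return arrays/vectors.
#' @examples
#' x <- array(1, c(3, 3, 1))
#' w <- array(1, c(3, 3, 1, 1))
#' conv2d_forward(x, w, 0)  # single value 9
#' @name layer-ops
NULL

#' @rdname layer-ops
#' @export
conv2d_forward <- function(input, weights, biases) {
  if (length(dim(input)) != 3L)
    stop_bad("'input' must be a (height, width, channels) array")
  cpp_conv2d(input, weights, as.numeric(biases))
}

#' @rdname layer-ops
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' @rdname layer-ops
#' @export
maxpool2x2_forward <- function(input) cpp_maxpool2(input)

#' @rdname layer-ops
#' @export
global_maxpool_forward <- function(input) cpp_global_maxpool(input)

#' @rdname layer-ops
#' @export
dense_forward <- function(input, weights, biases) {
  input <- as.numeric(input)
  if (length(input) != nrow(weights))
    stop_bad("input length (%d) does not match weight rows (%d)",
             length(input), nrow(weights))
  as.numeric(crossprod(weights, input)) + as.numeric(biases)
}

#' Loss and class probabilities from output logits
#'
#' @param logits numeric vector of length `n_classes`.
#' @param target_class 0-based class index of the true class.
#' @param loss a [loss_spec()].
#' @return list with `loss` (scalar), `prob` (per-class probabilities;
#'   independent sigmoids under `"bce"`, a simplex under `"softmax"`) and
#'   `predicted` (0-based argmax class).
#' @examples
#' loss_and_output(c(0, 0, 0), target_class = 1, loss_spec())$loss  # log(2)
#' @export
loss_and_output <- function(logits, target_class, loss = loss_spec()) {
  logits <- as.numeric(logits)
  K <- length(logits)
  if (target_class < 0 || target_class >= K)
    stop_bad("target_class %d out of range [0, %d)", target_class, K)
  eps <- loss$clip_epsilon
  y <- as.numeric(seq_len(K) - 1L == target_class)
  if (loss$variant == "bce") {
    p <- 1 / (1 + exp(-logits))
    pc <- pmin(pmax(p, eps), 1 - eps)
    l <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  } else {
    e <- exp(logits - max(logits))
    p <- e / sum(e)
    l <- -log(min(max(p[target_class + 1L], eps), 1 - eps))
  }
  list(loss = l, prob = p, predicted = which.max(p) - 1L)
}

#' Forward pass of the full network, optionally with phase-aware dropout
#'
#' Runs images through the network.  Dropout is applied to the fully
#' connected layer only when the running `phase` matches the policy's phase;
#' a fresh mask is sampled per batch of `batch_size` images (from the
#' current RNG state) and the masks used are returned for audit or for the
#' backward pass.  With `policy = NULL` or a `"none"` policy this is the
#' plain deterministic forward pass.
#'
#' @param params a `"network_params"` object.
#' @param images `(h, w, n)` array, `(h, w, 1, n)` array, or a
#'   [glyph_dataset()].
#' @param policy a [dropout_policy()] or `NULL`.
#' @param phase the phase being executed, `"train"` or `"test"`.
#' @param batch_size images per mask draw when dropout is active.
#' @return list with `logits` (`n x n_classes` matrix), `prob`, `fc`
#'   (`n x fc_units` post-dropout activations), `latent`, and `masks`
#'   (`fc_units x n_batches` 0/1 matrix, or `NULL` when inactive).
#' @export
network_forward <- function(params, images, policy = NULL,
                            phase = c("test", "train"), batch_size = 10L) {
  phase <- match.arg(phase)
  stopifnot(inherits(params, "network_params"))
  X <- as_image_cube(images, attr(params, "shapes"))
  eng <- shapes_for_engine(attr(params, "shapes"), attr(params, "n_classes"))
  active <- !is.null(policy) && policy$phase == phase && policy$rate > 0
  n <- dim(X)[3L]
  if (!active) {
    out <- cpp_net_forward(params, eng, X, numeric(0), 1)
    masks <- NULL
    logits <- t(out$logits); fc <- t(out$fc); lat <- t(out$latent)
  } else {
    scale <- if (isTRUE(policy$rescale)) 1 / (1 - policy$rate) else 1
    starts <- seq(1L, n, by = batch_size)
    masks <- matrix(0, eng$fc_units, length(starts))
    logits <- matrix(0, n, eng$n_classes)
    fc <- matrix(0, n, eng$fc_units)
    lat <- matrix(0, n, eng$filters2)
    for (b in seq_along(starts)) {
      idx <- starts[b]:min(starts[b] + batch_size - 1L, n)
      m <- sample_mask(eng$fc_units, policy$rate)
      masks[, b] <- m$keep
      out <- cpp_net_forward(params, eng, X[, , idx, drop = FALSE],
                             as.numeric(m$keep), scale)
      logits[idx, ] <- t(out$logits)
      fc[idx, ] <- t(out$fc)
      lat[idx, ] <- t(out$latent)
    }
  }
  prob <- 1 / (1 + exp(-logits))
  list(logits = logits, prob = prob, fc = fc, latent = lat, masks = masks)
}

#' Gradients of the batch-mean loss
#'
#' Backpropagation through the full network: gradients route only through
#' pooling argmax positions, dropped fully-connected units contribute zero
#' gradient, and kept units carry the inverted-dropout scaling.
#'
#' @inheritParams network_forward
#' @param labels 0-based integer class labels, one per image.
#' @param loss a [loss_spec()].
#' @param mask optional 0/1 keep vector over the fully connected layer (a
#'   [sample_mask()] result or plain vector); `NULL` for no dropout.
#' @param rate dropout rate the mask was drawn at (sets the inverted
#'   scaling of kept units).
#' @return list with `loss` (batch-mean) and `grads`, a list of arrays with
#'   the same shapes as `params`.
#' @export
backward_pass <- function(params, images, labels, loss = loss_spec(),
                          mask = NULL, rate = 0) {
  stopifnot(inherits(params, "network_params"))
  X <- as_image_cube(images, attr(params, "shapes"))
  eng <- shapes_for_engine(attr(params, "shapes"), attr(params, "n_classes"))
  m <- numeric(0)
  scale <- 1
  if (!is.null(mask)) {
    m <- as.numeric(if (inherits(mask, "dropout_mask")) mask$keep else mask)
    rate <- check_fraction(rate, "rate", open_hi = TRUE)
    if (rate > 0) scale <- 1 / (1 - rate)
  }
  cpp_net_grad(params, eng, X, as.integer(labels), m, scale,
               loss_code(loss), loss$clip_epsilon)
}

#' One plain stochastic-gradient step
#'
#' @param params a `"network_params"` object (or bare list of arrays).
#' @param grads gradients with the same shapes (e.g. from [backward_pass()]).
#' @param learning_rate positive step size.
#' @return Updated parameters, `params - learning_rate * grads`.
#' @export
sgd_update <- function(params, grads, learning_rate) {
  if (!is.numeric(learning_rate) || length(learning_rate) != 1L ||
      learning_rate <= 0)
    stop_bad("'learning_rate' must be a single positive number")
  if (!all(vapply(grads, function(g) all(is.finite(g)), TRUE)))
    stop_bad("non-finite gradients passed to sgd_update")
  out <- params
  for (nm in names(out)[names(out) %in% names(grads)]) {
    out[[nm]] <- out[[nm]] - learning_rate * grads[[nm]]
  }
  out
}

#' Check analytic gradients against central finite differences
#'
#' The independent oracle for the backward pass: every parameter is
#' perturbed by `±h` and the analytic gradient of the batch-mean loss is
#' compared with `(L(+h) - L(-h)) / 2h`.  Intended for small networks and
#' batches where the O(#parameters) cost is acceptable.
#'
#' @inheritParams backward_pass
#' @param h finite-difference step.
#' @param tolerance maximum acceptable relative error.
#' @return list with `pass`, `max_rel_error`, `worst_param`, and a named
#'   vector `per_param` of worst relative errors per parameter array.
#'   Relative error is `|a - f| / max(|a| + |f|, 1e-8)`.
#' @export
gradient_check <- function(params, images, labels, loss = loss_spec(),
                           mask = NULL, rate = 0, h = 1e-5,
                           tolerance = 1e-4) {
  stopifnot(inherits(params, "network_params"))
  X <- as_image_cube(images, attr(params, "shapes"))
  eng <- shapes_for_engine(attr(params, "shapes"), attr(params, "n_classes"))
  m <- numeric(0)
  scale <- 1
  if (!is.null(mask)) {
    m <- as.numeric(if (inherits(mask, "dropout_mask")) mask$keep else mask)
    if (rate > 0) scale <- 1 / (1 - rate)
  }
  labels <- as.integer(labels)
  code <- loss_code(loss)
  eps <- loss$clip_epsilon
  analytic <- cpp_net_grad(params, eng, X, labels, m, scale, code, eps)$grads
  per <- numeric(0)
  worst <- 0
  for (nm in names(analytic)) {
    a <- analytic[[nm]]
    f <- array(0, dim = dim(a) %||% length(a))
    for (i in seq_along(a)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      lp <- cpp_net_loss(pp, eng, X, labels, m, scale, code, eps)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      lm <- cpp_net_loss(pp, eng, X, labels, m, scale, code, eps)
      f[i] <- (lp - lm) / (2 * h)
    }
    rel <- abs(a - f) / pmax(abs(a) + abs(f), 1e-8)
    per[nm] <- max(rel)
    worst <- max(worst, per[nm])
  }
  list(pass = worst < tolerance, max_rel_error = worst,
       worst_param = names(per)[which.max(per)], per_param = per)
}

# Coerce datasets / arrays to the (h, w, n) cube the engine expects.
as_image_cube <- function(images, shapes) {
  if (inherits(images, "glyph_dataset")) images <- images$images
  d <- dim(images)
  if (is.null(d)) stop_bad("'images' must be an array")
  if (length(d) == 2L) {
    images <- array(images, dim = c(d, 1L))
    d <- dim(images)
  }
  if (length(d) == 4L) {
    if (d[3L] != 1L) stop_bad("only single-channel images are supported")
    images <- array(images, dim = d[c(1L, 2L, 4L)])
    d <- dim(images)
  }
  if (length(d) != 3L) stop_bad("'images' must have 2, 3 or 4 dimensions")
  if (!is.null(shapes) &&
      (d[1L] != shapes$input_rows || d[2L] != shapes$input_cols))
    stop_bad("images are %dx%d but the network expects %dx%d",
             d[1L], d[2L], shapes$input_rows, shapes$input_cols)
  images
}
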