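#' Train an engram-like convolutional classifier
#'
#' The central fitting function: trains the two-convolution network on a
#' glyph dataset by plain stochastic gradient descent, with dropout of the
#' fully connected ("engram") layer governed by a [dropout_policy()].  At
#' the end of every epoch the mean training loss and, if `test` is given,
#' the test accuracy and test loss are recorded — test-phase dropout
#' policies apply fresh masks just prior to each evaluation batch, while
#' train-phase policies are inert at evaluation (standard inference).
#'
#' All randomness (initialization, per-epoch shuffling, train masks, test
#' masks) is derived from `seed` through independent streams, so runs are
#' bit-reproducible and conditions that share a seed see identical data
#' order and initial weights regardless of their dropout policy.
#'
#' @param train a [glyph_dataset()] to learn from.
#' @param test optional [glyph_dataset()] evaluated at the end of each
#'   epoch.
#' @param dropout a [dropout_policy()].
#' @param epochs number of complete passes over the training data.
#' @param batch_size images per gradient step; the final short batch is
#'   included.
#' @param learning_rate SGD step size.
#' @param loss a [loss_spec()].
#' @param shapes a [layer_shapes()]; the default is the standard geometry.
#' @param seed master seed for this run.
#' @param init_params optional `"network_params"` to start from (e.g. a
#'   transferred network); must match `shapes` and the class count.
#' @param shuffle logical; reshuffle the training order each epoch.
#' @param verbose print progress every `verbose` epochs (0 = silent,
#'   `TRUE` = every 10).
#' @return An object of class `"engram_net"`: list with `params`,
#'   `history` (data.frame `epoch`, `train_loss`, `test_accuracy`,
#'   `test_loss`), `policy`, `config`, `shapes`, `n_classes`,
#'   `class_names`.
#' @examples
#' \donttest{
#' tr <- generate_dataset("digits", 100, seed = 1)
#' te <- generate_dataset("digits", 50, seed = 2)
#' fit <- engram_net(tr, te, epochs = 3, seed = 1)
#' fit$history
#' }
#' @export
engram_net <- function(train, test = NULL,
                       dropout = dropout_policy("none"),
                       epochs = 100L, batch_size = 10L, learning_rate = 0.01,
                       loss = loss_spec(), shapes = layer_shapes(),
                       seed = 1L, init_params = NULL, shuffle = TRUE,
                       verbose = 0) {
  stopifnot(inherits(train, "glyph_dataset"),
            inherits(dropout, "dropout_policy"),
            inherits(loss, "loss_spec"))
  epochs <- check_count(epochs, "epochs")
  batch_size <- check_count(batch_size, "batch_size")
  seed <- check_count(seed, "seed", min = 0L)
  if (learning_rate < 0)
    stop_bad("'learning_rate' must be non-negative")
  n_classes <- train$n_classes
  if (!is.null(test) && test$n_classes != n_classes)
    stop_bad("train and test class counts differ (%d vs %d)",
             n_classes, test$n_classes)

  init_seed <- sub_seed(seed, 1L)
  shuffle_seed <- sub_seed(seed, 2L)
  train_mask_seed <- sub_seed(seed, 3L)
  test_mask_seed <- sub_seed(seed, 4L)

  params <- if (is.null(init_params)) {
    init_network(shapes, n_classes, seed = init_seed)
  } else {
    stopifnot(inherits(init_params, "network_params"))
    if (attr(init_params, "n_classes") != n_classes)
      stop_bad("init_params has %d output units but the data has %d classes",
               attr(init_params, "n_classes"), n_classes)
    init_params
  }
  eng <- shapes_for_engine(shapes, n_classes)
  X <- as_image_cube(train, shapes)
  n <- dim(X)[3L]
  nbatch <- ceiling(n / batch_size)
  scale <- if (dropout$rate > 0 && isTRUE(dropout$rescale))
    1 / (1 - dropout$rate) else 1
  code <- loss_code(loss)
  eps <- loss$clip_epsilon
  if (isTRUE(verbose)) verbose <- 10

  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        test_accuracy = NA_real_, test_loss = NA_real_)
  p <- unclass(params)[c("W1", "b1", "W2", "b2", "Wf", "bf", "Wo", "bo")]
  no_mask <- matrix(numeric(0), nrow = 0, ncol = 0)

  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) {
      with_seed(sub_seed(shuffle_seed, ep), sample.int(n)) - 1L
    } else {
      seq_len(n) - 1L
    }
    masks <- if (dropout$phase == "train" && dropout$rate > 0) {
      ncolm <- if (dropout$per_sample) n else nbatch
      with_seed(sub_seed(train_mask_seed, ep),
                mask_matrix(eng$fc_units, dropout$rate, ncolm))
    } else {
      no_mask
    }
    res <- cpp_train_epoch(p, eng, X, train$labels, ord, batch_size,
                           learning_rate, masks, scale, code, eps)
    p <- res$params
    history$train_loss[ep] <- res$loss

    if (!is.null(test)) {
      ev <- evaluate_engine(p, eng, test, dropout, loss, batch_size,
                            mask_seed = sub_seed(test_mask_seed, ep))
      history$test_accuracy[ep] <- ev$accuracy
      history$test_loss[ep] <- ev$loss
    }
    if (verbose > 0 && (ep %% verbose == 0 || ep == epochs)) {
      message(sprintf("epoch %4d  train loss %.4f%s", ep, res$loss,
                      if (!is.null(test))
                        sprintf("  test acc %.3f", history$test_accuracy[ep])
                      else ""))
    }
  }

  params_out <- structure(p, class = "network_params", shapes = shapes,
                          n_classes = n_classes,
                          init_seed = attr(params, "init_seed") %||% init_seed)
  structure(list(
    params = params_out,
    history = history,
    policy = dropout,
    loss = loss,
    config = list(epochs = epochs, batch_size = batch_size,
                  learning_rate = learning_rate, seed = seed,
                  shuffle = shuffle, n_train = n,
                  n_test = if (is.null(test)) 0L else length(test$labels)),
    shapes = shapes,
    n_classes = n_classes,
    class_names = train$class_names
  ), class = "engram_net")
}

# Shared evaluation path: test-phase policies draw one fresh mask per
# evaluation batch from `mask_seed`; anything else is plain inference.
evaluate_engine <- function(p, eng, data, policy, loss, batch_size,
                            mask_seed) {
  X <- as_image_cube(data, NULL)
  n <- dim(X)[3L]
  nb <- ceiling(n / batch_size)
  if (!is.null(policy) && policy$phase == "test" && policy$rate > 0) {
    masks <- with_seed(mask_seed, mask_matrix(eng$fc_units, policy$rate, nb))
    scale <- if (isTRUE(policy$rescale)) 1 / (1 - policy$rate) else 1
  } else {
    masks <- matrix(numeric(0), 0, 0)
    scale <- 1
  }
  cpp_evaluate(p, eng, X, data$labels, batch_size, masks, scale,
               loss_code(loss), loss$clip_epsilon)
}

#' Run one training epoch
#'
#' Low-level single-epoch step used by [engram_net()]: one seeded shuffle,
#' sequential batches (final short batch included), forward with
#' train-phase dropout per the policy, backpropagation, and an SGD update
#' per batch.
#'
#' @param params a `"network_params"` object.
#' @param train a [glyph_dataset()].
#' @param policy a [dropout_policy()].
#' @param batch_size,learning_rate,loss as in [engram_net()].
#' @param shuffle_seed,mask_seed integer seeds for this epoch's data order
#'   and dropout masks.
#' @param shuffle logical.
#' @return list with updated `params` and `loss` (mean per-sample training
#'   loss).
#' @export
train_epoch <- function(params, train, policy = dropout_policy("none"),
                        batch_size = 10L, learning_rate = 0.01,
                        loss = loss_spec(), shuffle_seed = 1L,
                        mask_seed = 1L, shuffle = TRUE) {
  stopifnot(inherits(params, "network_params"),
            inherits(train, "glyph_dataset"))
  shapes <- attr(params, "shapes")
  eng <- shapes_for_engine(shapes, attr(params, "n_classes"))
  X <- as_image_cube(train, shapes)
  n <- dim(X)[3L]
  nbatch <- ceiling(n / batch_size)
  ord <- if (shuffle) with_seed(shuffle_seed, sample.int(n)) - 1L
         else seq_len(n) - 1L
  if (policy$phase == "train" && policy$rate > 0) {
    ncolm <- if (policy$per_sample) n else nbatch
    masks <- with_seed(mask_seed, mask_matrix(eng$fc_units, policy$rate, ncolm))
    scale <- if (isTRUE(policy$rescale)) 1 / (1 - policy$rate) else 1
  } else {
    masks <- matrix(numeric(0), 0, 0)
    scale <- 1
  }
  res <- cpp_train_epoch(unclass(params), eng, X, train$labels, ord,
                         batch_size, learning_rate, masks, scale,
                         loss_code(loss), loss$clip_epsilon)
  res$params <- structure(res$params, class = "network_params",
                          shapes = shapes,
                          n_classes = attr(params, "n_classes"),
                          init_seed = attr(params, "init_seed"))
  res
}

#' Evaluate a network on a dataset
#'
#' Accuracy is the fraction of argmax predictions equal to the labels;
#' loss is the mean per-sample loss.  Test-phase dropout policies are
#' applied with a fresh mask per evaluation batch; train-phase and `"none"`
#' policies evaluate deterministically.
#'
#' @param object an [engram_net()] fit or a `"network_params"` object.
#' @param data a [glyph_dataset()].
#' @param policy a [dropout_policy()] (defaults to no dropout).
#' @param loss a [loss_spec()].
#' @param batch_size evaluation batch size (mask granularity).
#' @param mask_seed seed for test-phase masks.
#' @return list with `accuracy` and `loss`.
#' @export
evaluate_network <- function(object, data, policy = dropout_policy("none"),
                             loss = loss_spec(), batch_size = 10L,
                             mask_seed = 1L) {
  params <- if (inherits(object, "engram_net")) object$params else object
  stopifnot(inherits(params, "network_params"),
            inherits(data, "glyph_dataset"))
  eng <- shapes_for_engine(attr(params, "shapes"), attr(params, "n_classes"))
  evaluate_engine(unclass(params), eng, data, policy, loss, batch_size,
                  mask_seed)
}

#' Transfer a trained network to a new class inventory
#'
#' Implements head replacement for transfer learning: the convolutional
#' and fully connected parameters are copied bit-exactly, the output layer
#' is stripped and re-initialized for `n_new_classes`, and all layers
#' remain trainable in retraining.
#'
#' @param object an [engram_net()] fit or `"network_params"` object trained
#'   on the source task.
#' @param n_new_classes class count of the new task (>= 2).
#' @param head_seed seed for the new output head's initialization.
#' @return A `"network_params"` object for the new task.
#' @export
transfer_network <- function(object, n_new_classes, head_seed = 1L) {
  params <- if (inherits(object, "engram_net")) object$params else object
  stopifnot(inherits(params, "network_params"))
  n_new_classes <- check_count(n_new_classes, "n_new_classes", min = 2L)
  shapes <- attr(params, "shapes")
  fresh <- init_network(shapes, n_new_classes, seed = head_seed)
  out <- params
  out$Wo <- fresh$Wo
  out$bo <- fresh$bo
  attr(out, "n_classes") <- n_new_classes
  out
}

#' @export
print.engram_net <- function(x, ...) {
  cat("Engram-network classifier fit\n")
  cat(sprintf("  %d classes, %s parameters\n", x$n_classes,
              format(n_parameters(x$params), big.mark = ",")))
  print(x$policy)
  cat(sprintf("  trained %d epochs, batch %d, lr %g, %s loss, seed %d\n",
              x$config$epochs, x$config$batch_size, x$config$learning_rate,
              x$loss$variant, x$config$seed))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f", last$train_loss))
  if (!is.na(last$test_accuracy))
    cat(sprintf(", test accuracy %.3f", last$test_accuracy))
  cat("\n")
  invisible(x)
}

#' @export
summary.engram_net <- function(object, ...) {
  h <- object$history
  out <- list(
    n_classes = object$n_classes,
    policy = object$policy,
    epochs = object$config$epochs,
    final_train_loss = h$train_loss[nrow(h)],
    final_test_accuracy = h$test_accuracy[nrow(h)],
    final_test_loss = h$test_loss[nrow(h)],
    best_test_accuracy = if (all(is.na(h$test_accuracy))) NA_real_
                         else max(h$test_accuracy, na.rm = TRUE)
  )
  class(out) <- "summary.engram_net"
  out
}

#' @export
print.summary.engram_net <- function(x, ...) {
  cat(sprintf("engram_net: %d classes, %d epochs\n", x$n_classes, x$epochs))
  print(x$policy)
  cat(sprintf("  final train loss     %.4f\n", x$final_train_loss))
  if (!is.na(x$final_test_accuracy)) {
    cat(sprintf("  final test accuracy  %.3f\n", x$final_test_accuracy))
    cat(sprintf("  best  test accuracy  %.3f\n", x$best_test_accuracy))
  }
  invisible(x)
}

#' @export
coef.engram_net <- function(object, ...) object$params

#' Predict classes or probabilities for new images
#'
#' Standard inference of a (possibly dropout-trained) network: no dropout
#' is applied unless an explicit test-phase `policy` is passed.
#'
#' @param object an [engram_net()] fit.
#' @param newdata a [glyph_dataset()] or image array.
#' @param type `"class"` (default), `"prob"` or `"logits"`.
#' @param policy optional [dropout_policy()] applied at prediction.
#' @param mask_seed seed for test-phase masks, if any.
#' @param ... ignored.
#' @return For `"class"`, a character vector of predicted class names (with
#'   the 0-based index in attribute `"index"`); otherwise an `n x
#'   n_classes` matrix.
#' @export
predict.engram_net <- function(object, newdata, type = c("class", "prob",
                                                         "logits"),
                               policy = NULL, mask_seed = 1L, ...) {
  type <- match.arg(type)
  out <- if (!is.null(policy) && policy$phase == "test" && policy$rate > 0) {
    with_seed(mask_seed,
              network_forward(object$params, newdata, policy, phase = "test",
                              batch_size = object$config$batch_size))
  } else {
    network_forward(object$params, newdata, NULL)
  }
  if (type == "logits") return(out$logits)
  if (type == "prob") return(out$prob)
  idx <- max.col(out$logits, ties.method = "first") - 1L
  structure(object$class_names[idx + 1L], index = idx)
}

#' Plot learning curves of a fit
#'
#' @param x an [engram_net()] fit.
#' @param which metrics to draw, subset of `c("train_loss",
#'   "test_accuracy", "test_loss")`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.engram_net <- function(x, which = c("train_loss", "test_accuracy"),
                            ...) {
  h <- x$history
  which <- intersect(which, names(h)[colSums(!is.na(h)) > 0])
  if (!length(which)) stop_bad("no recorded metrics to plot")
  op <- graphics::par(mfrow = c(1, length(which)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (m in which) {
    graphics::plot(h$epoch, h[[m]], type = "l", xlab = "epoch",
                   ylab = gsub("_", " ", m), ...)
  }
  invisible(x)
}
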