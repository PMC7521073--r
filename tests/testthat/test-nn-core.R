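# Core network engine: layer operations, loss, initialization, SGD, and the
# finite-difference gradient oracle.

test_that("valid-convolution shape chain reproduces the standard geometry", {
  sh <- layer_shapes()
  expect_equal(sh$conv1_out, c(26, 26, 32))
  expect_equal(sh$pool1_out, c(13, 13, 32))
  expect_equal(sh$conv2_out, c(11, 11, 64))
  expect_equal(sh$pool2_out, c(5, 5, 64))
  expect_equal(sh$latent, 64)
  expect_equal(sh$fc_units, 100)
})

test_that("conv2d_forward computes the valid convolution", {
  # closed form: all-ones 3x3 input and filter, zero bias -> 9
  x <- array(1, c(3, 3, 1))
  w <- array(1, c(3, 3, 1, 1))
  out <- conv2d_forward(x, w, 0)
  expect_equal(dim(out), c(1L, 1L, 1L))
  expect_equal(as.numeric(out), 9)

  # shape arithmetic on the real geometry
  set.seed(1)
  x28 <- array(runif(28 * 28), c(28, 28, 1))
  w32 <- array(rnorm(3 * 3 * 1 * 32, sd = 0.1), c(3, 3, 1, 32))
  expect_equal(dim(conv2d_forward(x28, w32, numeric(32))), c(26L, 26L, 32L))

  # linearity: zero input with zero bias -> zero; scaling input scales output
  expect_equal(as.numeric(conv2d_forward(array(0, c(5, 5, 2)),
                                         array(rnorm(2 * 2 * 2 * 3),
                                               c(2, 2, 2, 3)),
                                         numeric(3))),
               rep(0, 4 * 4 * 3))
  xs <- array(runif(5 * 5 * 2), c(5, 5, 2))
  ws <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  expect_equal(conv2d_forward(2 * xs, ws, numeric(3)),
               2 * conv2d_forward(xs, ws, numeric(3)))

  # brute-force oracle: explicit loop over a small case
  oracle <- function(x, w, b) {
    oh <- dim(x)[1] - dim(w)[1] + 1
    ow <- dim(x)[2] - dim(w)[2] + 1
    out <- array(0, c(oh, ow, dim(w)[4]))
    for (f in seq_len(dim(w)[4])) for (i in seq_len(oh)) for (j in seq_len(ow)) {
      s <- b[f]
      for (ic in seq_len(dim(x)[3])) for (ki in seq_len(dim(w)[1]))
        for (kj in seq_len(dim(w)[2]))
          s <- s + x[i + ki - 1, j + kj - 1, ic] * w[ki, kj, ic, f]
      out[i, j, f] <- s
    }
    out
  }
  expect_equal(conv2d_forward(xs, ws, c(1, -1, 0.5)),
               oracle(xs, ws, c(1, -1, 0.5)), tolerance = 1e-12)

  expect_error(conv2d_forward(array(0, c(2, 2, 1)),
                              array(0, c(3, 3, 1, 1)), 0),
               "larger than input")
})

test_that("relu is the elementwise ramp and is idempotent", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  x <- matrix(abs(rnorm(12)), 3)
  expect_equal(relu(x), x)
  set.seed(4)
  y <- array(rnorm(24), c(2, 3, 4))
  expect_equal(relu(relu(y)), relu(y))
  expect_equal(dim(relu(y)), dim(y))
})

test_that("2x2 max pooling halves dimensions, drops odd trailing edges", {
  out <- maxpool2x2_forward(array(c(1, 3, 2, 4), c(2, 2, 1)))
  expect_equal(as.numeric(out$output), 4)

  # 11x11 pools to 5x5, completing the chain 28 -> 26 -> 13 -> 11 -> 5
  set.seed(2)
  x <- array(runif(11 * 11 * 64), c(11, 11, 64))
  expect_equal(dim(maxpool2x2_forward(x)$output), c(5L, 5L, 64L))

  # constant map stays constant
  expect_equal(unique(as.numeric(maxpool2x2_forward(
    array(2.5, c(6, 6, 3)))$output)), 2.5)

  # argmax record points at the maximum
  p <- maxpool2x2_forward(x)
  ch <- x[1:2, 1:2, 7]
  expect_equal(p$output[1, 1, 7], max(ch))
  expect_error(maxpool2x2_forward(array(0, c(1, 4, 1))), "too small")
})

test_that("global max pooling extracts one feature per channel", {
  set.seed(3)
  x <- array(runif(5 * 5 * 64), c(5, 5, 64))
  g <- global_maxpool_forward(x)
  expect_length(g$output, 64)
  expect_equal(g$output, apply(x, 3, max))
  expect_equal(as.numeric(global_maxpool_forward(
    array(1.25, c(3, 3, 4)))$output), rep(1.25, 4))
})

test_that("dense layer is the affine map, against a double-loop oracle", {
  W <- matrix(rnorm(64 * 100), 64, 100)
  expect_length(dense_forward(runif(64), W, numeric(100)), 100)
  b <- rnorm(10)
  expect_equal(dense_forward(runif(5), matrix(0, 5, 10), b), b)

  set.seed(5)
  x <- rnorm(4); W2 <- matrix(rnorm(12), 4, 3); b2 <- rnorm(3)
  oracle <- numeric(3)
  for (j in 1:3) {
    s <- b2[j]
    for (i in 1:4) s <- s + x[i] * W2[i, j]
    oracle[j] <- s
  }
  expect_equal(dense_forward(x, W2, b2), oracle)
  expect_error(dense_forward(1:3, W2, b2), "does not match")
})

test_that("loss has the closed-form values and respects clipping", {
  # logits 0 -> all sigmoid probabilities 0.5 -> mean BCE = log(2)
  for (K in c(2, 10, 26)) {
    expect_equal(loss_and_output(numeric(K), 0, loss_spec())$loss, log(2),
                 tolerance = 1e-12)
  }
  # softmax uniform -> loss = log(K)
  expect_equal(loss_and_output(numeric(10), 3, loss_spec("softmax"))$loss,
               log(10), tolerance = 1e-12)

  # saturated perfect prediction -> loss ~ 0 within clip tolerance
  big <- c(50, -50, -50)
  out <- loss_and_output(big, 0, loss_spec())
  expect_lt(out$loss, 1e-6)
  expect_equal(out$predicted, 0)

  # loss finite even at extreme logits, in both variants
  expect_true(is.finite(loss_and_output(c(1e4, -1e4), 1, loss_spec())$loss))
  expect_true(is.finite(
    loss_and_output(c(1e4, -1e4), 1, loss_spec("softmax"))$loss))

  expect_error(loss_and_output(numeric(3), 3, loss_spec()), "out of range")
  expect_error(loss_spec(clip_epsilon = 0.5), "clip_epsilon")
})

test_that("initialization is seeded, shape-consistent, and validated", {
  p1 <- init_network(layer_shapes(), 10, seed = 7)
  p2 <- init_network(layer_shapes(), 10, seed = 7)
  expect_identical(p1$W1, p2$W1)
  expect_identical(p1$Wo, p2$Wo)
  expect_false(identical(p1$W1, init_network(layer_shapes(), 10, seed = 8)$W1))

  expect_equal(dim(p1$W1), c(3L, 3L, 1L, 32L))
  expect_equal(dim(p1$W2), c(3L, 3L, 32L, 64L))
  expect_equal(dim(p1$Wf), c(64L, 100L))
  expect_equal(dim(init_network(layer_shapes(), 26)$Wo), c(100L, 26L))
  expect_equal(unique(p1$b1), 0)

  expect_error(init_network(layer_shapes(), 1), "n_classes")
  expect_error(layer_shapes(input_size = 2, kernel = 3), "larger than input")
})

test_that("sgd_update is the elementwise descent step", {
  p <- init_network(tiny_shapes(), 3, seed = 1)
  zero <- lapply(p, function(x) x * 0)
  expect_equal(unclass(sgd_update(p, zero, 0.1))[names(p)],
               unclass(p)[names(p)])

  # lr = 1 with grad = params zeroes everything
  z <- sgd_update(p, unclass(p), 1)
  expect_true(all(vapply(z, function(x) all(x == 0), TRUE)))

  # linearity: two steps with g equal one step with 2g (fixed gradients)
  g <- lapply(unclass(p)[names(p)], function(x) x * 0.1)
  two <- sgd_update(sgd_update(p, g, 0.5), g, 0.5)
  one <- sgd_update(p, lapply(g, function(x) 2 * x), 0.5)
  expect_equal(unclass(two)[names(p)], unclass(one)[names(p)],
               tolerance = 1e-14)

  bad <- g; bad$b1[1] <- NaN
  expect_error(sgd_update(p, bad, 0.1), "non-finite")
})

test_that("analytic gradients match central finite differences", {
  b <- tiny_batch()
  p <- init_network(tiny_shapes(), 3, seed = 42)
  for (variant in c("bce", "softmax")) {
    gc <- gradient_check(p, b$images, b$labels, loss = loss_spec(variant))
    expect_lt(gc$max_rel_error, 1e-4)
  }
  # with pooling active
  shp <- layer_shapes(input_size = 10, kernel = 2, filters = c(2, 3),
                      fc_units = 4)
  pp <- init_network(shp, 3, seed = 1)
  set.seed(11)
  Xp <- array(runif(10 * 10 * 2), c(10, 10, 2))
  expect_lt(gradient_check(pp, Xp, c(1L, 2L))$max_rel_error, 1e-4)
})

test_that("a sign-flipped gradient is caught by the finite-difference oracle", {
  b <- tiny_batch()
  p <- init_network(tiny_shapes(), 3, seed = 42)
  bp <- backward_pass(p, b$images, b$labels)
  # independent R-side loss: forward logits + loss_and_output, averaged
  batch_loss <- function(params) {
    lg <- network_forward(params, b$images)$logits
    mean(vapply(seq_along(b$labels), function(i) {
      loss_and_output(lg[i, ], b$labels[i])$loss
    }, 0))
  }
  expect_equal(bp$loss, batch_loss(p), tolerance = 1e-10)
  h <- 1e-5
  fd <- numeric(length(p$bf))
  for (i in seq_along(p$bf)) {
    pp <- p; pp$bf[i] <- pp$bf[i] + h; up <- batch_loss(pp)
    pp$bf[i] <- pp$bf[i] - 2 * h; dn <- batch_loss(pp)
    fd[i] <- (up - dn) / (2 * h)
  }
  expect_equal(as.numeric(bp$grads$bf), fd, tolerance = 1e-6)
  flipped <- -bp$grads$bf
  rel <- abs(flipped - fd) / pmax(abs(flipped) + abs(fd), 1e-8)
  expect_gt(max(rel), 1e-4)
})

test_that("degenerate and stationary batches give finite, near-zero reports", {
  p <- init_network(tiny_shapes(), 3, seed = 2)
  zero_batch <- array(0, c(6, 6, 2))
  gc <- gradient_check(p, zero_batch, c(0L, 0L))
  expect_true(is.finite(gc$max_rel_error))

  # near-perfect prediction => loss and gradients at the clipped optimum
  b <- tiny_batch(n = 1L)
  p2 <- p
  p2$bo <- c(80, -80, -80)  # saturate class 0
  p2$Wo[] <- 0
  bp <- backward_pass(p2, b$images, 0L)
  expect_lt(bp$loss, 1e-6)
  expect_lt(max(abs(unlist(bp$grads))), 1e-6)
})

test_that("forward pass is deterministic and batch-size invariant", {
  p <- init_network(layer_shapes(), 10, seed = 3)
  set.seed(21)
  X <- array(runif(28 * 28 * 7), c(28, 28, 7))
  f1 <- network_forward(p, X)
  f2 <- network_forward(p, X)
  expect_identical(f1$logits, f2$logits)
  expect_equal(dim(f1$logits), c(7L, 10L))
  expect_equal(dim(f1$latent), c(7L, 64L))
  # single image forwarded alone equals its row in the batch
  f3 <- network_forward(p, X[, , 3, drop = FALSE])
  expect_equal(as.numeric(f3$logits), f1$logits[3, ], tolerance = 1e-12)
})
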