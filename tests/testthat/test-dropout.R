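# The engram-dropout operator: Bernoulli masks, inverted scaling, phase
# gating, and gradient blocking.

test_that("mask sampling follows the Bernoulli model", {
  set.seed(1)
  m0 <- sample_mask(100, 0)
  expect_equal(m0$keep, rep(1L, 100))
  expect_equal(m0$realized_drop_fraction, 0)
  expect_error(sample_mask(100, 1), "rate")
  expect_error(sample_mask(100, -0.1), "rate")

  # 10,000 draws at width 100, rate 0.8: mean realized fraction within 3
  # binomial standard errors of 0.8
  set.seed(42)
  fr <- replicate(10000, sample_mask(100, 0.8)$realized_drop_fraction)
  se <- sqrt(0.8 * 0.2 / (100 * 10000))
  expect_lt(abs(mean(fr) - 0.8), 3 * se)
  expect_true(all(sample_mask(50, 0.5)$keep %in% c(0L, 1L)))
})

test_that("apply_dropout zeroes dropped units and rescales kept ones", {
  expect_equal(apply_dropout(c(2, 4, 6, 8), c(1, 0, 1, 0), rate = 0.5),
               c(4, 0, 12, 0))
  x <- rnorm(10)
  expect_equal(apply_dropout(x, rep(1, 10), rate = 0), x)
  expect_equal(apply_dropout(c(1, 2), c(1, 0), rate = 0.5, rescale = FALSE),
               c(1, 0))
  expect_error(apply_dropout(1:3, c(1, 0), rate = 0.5), "mask length")
})

test_that("inverted dropout preserves expectation", {
  set.seed(7)
  x <- runif(100, 0.5, 2)
  n <- 10000
  acc <- numeric(100)
  for (i in seq_len(n)) {
    acc <- acc + apply_dropout(x, sample_mask(100, 0.5), rate = 0.5)
  }
  avg <- acc / n
  se <- x * sqrt(0.5 / 0.5) / sqrt(n)  # sd of x*k/(1-r) is x*sqrt(r/(1-r))
  expect_true(all(abs(avg - x) < 3 * se))
})

test_that("dropout is applied only when the phase matches the policy", {
  p <- init_network(layer_shapes(), 10, seed = 5)
  set.seed(31)
  X <- array(runif(28 * 28 * 20), c(28, 28, 20))

  plain <- network_forward(p, X)
  # no policy vs explicit none-policy: bit-identical
  expect_identical(plain$logits,
                   network_forward(p, X, dropout_policy("none"))$logits)
  # train-phase policy is inert at evaluation
  expect_identical(plain$logits,
                   network_forward(p, X, dropout_policy("train", 0.5),
                                   phase = "test")$logits)
  # train-phase policy is active in the train phase
  set.seed(1)
  masked <- network_forward(p, X, dropout_policy("train", 0.5),
                            phase = "train")
  expect_false(identical(plain$logits, masked$logits))
  expect_false(is.null(masked$masks))
})

test_that("test-phase dropout zeroes about rate x width units per sample", {
  p <- init_network(layer_shapes(), 10, seed = 5)
  set.seed(31)
  X <- array(runif(28 * 28 * 40), c(28, 28, 40))
  set.seed(99)
  out <- network_forward(p, X, dropout_policy("test", 0.5), phase = "test",
                         batch_size = 10)
  # ReLU already zeroes some units; count exactly the mask-dropped ones
  dropped <- vapply(seq_len(4), function(b) sum(out$masks[, b] == 0), 0)
  n <- 4 * 100
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(dropped / 100) - 0.5), 3 * se + 0.05)
  # dropped mask positions are exactly zero in the fc activations
  for (b in seq_len(4)) {
    rows <- ((b - 1) * 10 + 1):(b * 10)
    expect_true(all(out$fc[rows, out$masks[, b] == 0] == 0))
  }
})

test_that("fresh masks are drawn per batch", {
  p <- init_network(layer_shapes(), 10, seed = 5)
  set.seed(13)
  X <- array(runif(28 * 28 * 50), c(28, 28, 50))
  set.seed(2)
  out <- network_forward(p, X, dropout_policy("test", 0.5), phase = "test",
                         batch_size = 10)
  expect_equal(ncol(out$masks), 5)
  # probability of any two identical 100-unit masks is ~ 2^-100
  expect_gt(nrow(unique(t(out$masks))), 1)
})

test_that("dropped units contribute zero gradient", {
  b <- tiny_batch(n = 4L)
  p <- init_network(tiny_shapes(fc = 6L), 3, seed = 8)
  mask <- c(1, 0, 1, 0, 0, 1)
  bp <- backward_pass(p, b$images, b$labels, mask = mask, rate = 0.5)
  dropped <- which(mask == 0)
  expect_true(all(bp$grads$Wo[dropped, ] == 0))
  expect_true(all(bp$grads$bf[dropped] == 0))
  expect_true(all(bp$grads$Wf[, dropped] == 0))
  kept <- which(mask == 1)
  expect_gt(max(abs(bp$grads$Wf[, kept])), 0)
  # analytic gradients under a fixed mask still match finite differences
  gc <- gradient_check(p, b$images, b$labels, mask = mask, rate = 0.5)
  expect_lt(gc$max_rel_error, 1e-4)
})

test_that("a none policy leaves the training engine mask-free", {
  tr <- generate_dataset("digits", 40, seed = 1)
  f1 <- engram_net(tr, epochs = 2, seed = 3)
  f2 <- engram_net(tr, epochs = 2, seed = 3, dropout = dropout_policy("none"))
  expect_identical(f1$params$W1, f2$params$W1)
  expect_identical(f1$history, f2$history)
})
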