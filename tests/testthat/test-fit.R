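# The engram_net fitting function, its methods, evaluation, and transfer.

test_that("fitting returns a complete, reproducible engram_net object", {
  tr <- generate_dataset("digits", 60, seed = 1)
  te <- generate_dataset("digits", 40, seed = 2)
  fit <- engram_net(tr, te, epochs = 3, seed = 5)
  expect_s3_class(fit, "engram_net")
  expect_equal(fit$history$epoch, 1:3)
  expect_false(anyNA(fit$history$train_loss))
  expect_true(all(fit$history$test_accuracy >= 0 &
                  fit$history$test_accuracy <= 1))
  expect_true(all(fit$history$train_loss >= 0))
  expect_true(all(fit$history$test_loss >= 0))

  fit2 <- engram_net(tr, te, epochs = 3, seed = 5)
  expect_identical(fit$params$W1, fit2$params$W1)
  expect_identical(fit$params$Wo, fit2$params$Wo)
  expect_identical(fit$history, fit2$history)
  expect_false(identical(fit$params$W1,
                         engram_net(tr, te, epochs = 3, seed = 6)$params$W1))

  expect_output(print(fit), "Engram-network classifier")
  expect_s3_class(summary(fit), "summary.engram_net")
  expect_s3_class(coef(fit), "network_params")
})

test_that("a zero learning rate is the identity and reports the initial loss", {
  tr <- generate_dataset("digits", 40, seed = 3)
  fit <- engram_net(tr, epochs = 1, learning_rate = 0, seed = 2)
  init <- init_network(layer_shapes(), 10,
                       seed = attr(fit$params, "init_seed"))
  expect_identical(fit$params$W1, init$W1)
  expect_identical(fit$params$Wo, init$Wo)
  ev <- evaluate_network(init, tr)
  expect_equal(fit$history$train_loss[1], ev$loss, tolerance = 1e-12)
})

test_that("training reduces the loss on synthetic digits for most seeds", {
  wins <- 0
  for (s in 1:5) {
    tr <- generate_dataset("digits", 100, seed = 100 + s)
    fit <- engram_net(tr, epochs = 5, seed = s)
    wins <- wins + (fit$history$train_loss[5] < fit$history$train_loss[1])
  }
  expect_gte(wins, 4)
})

test_that("an untrained network scores at chance on balanced data", {
  correct <- 0; total <- 0
  for (s in 1:5) {
    te <- generate_dataset("digits", 200, seed = 200 + s)
    p <- init_network(layer_shapes(), 10, seed = s)
    correct <- correct + evaluate_network(p, te)$accuracy * 200
    total <- total + 200
  }
  se <- sqrt(0.1 * 0.9 / total)
  expect_lt(abs(correct / total - 0.1), 3 * se + 0.01)
})

test_that("a saturable toy problem is memorized perfectly", {
  d <- generate_dataset(c("0", "1"), 4, seed = 7,
                        params = glyph_gen_params(noise_sd = 0.01))
  fit <- engram_net(d, epochs = 150, learning_rate = 0.05, batch_size = 2,
                    seed = 1)
  expect_equal(evaluate_network(fit, d)$accuracy, 1.0)
})

test_that("evaluation applies dropout only under a test-phase policy", {
  tr <- generate_dataset("digits", 60, seed = 4)
  p <- init_network(layer_shapes(), 10, seed = 9)
  plain <- evaluate_network(p, tr)
  inert <- evaluate_network(p, tr, policy = dropout_policy("train", 0.5))
  expect_identical(plain, inert)
  masked <- evaluate_network(p, tr, policy = dropout_policy("test", 0.5))
  expect_false(identical(plain$loss, masked$loss))
  # seeded test masks reproduce
  expect_identical(masked,
                   evaluate_network(p, tr,
                                    policy = dropout_policy("test", 0.5)))
})

test_that("predict returns class names, probabilities, and logits", {
  tr <- generate_dataset("digits", 60, seed = 1)
  fit <- engram_net(tr, epochs = 2, seed = 1)
  te <- generate_dataset("digits", 15, seed = 2)
  cls <- predict(fit, te)
  expect_length(cls, 15)
  expect_true(all(cls %in% as.character(0:9)))
  pr <- predict(fit, te, type = "prob")
  expect_equal(dim(pr), c(15L, 10L))
  expect_true(all(pr >= 0 & pr <= 1))
  lg <- predict(fit, te, type = "logits")
  expect_equal(as.integer(attr(cls, "index")),
               max.col(lg, ties.method = "first") - 1L)
})

test_that("transfer copies the body bit-exactly and re-initializes the head", {
  tr <- generate_dataset("digits", 60, seed = 1)
  fit <- engram_net(tr, epochs = 2, seed = 3)
  moved <- transfer_network(fit, 26, head_seed = 11)
  expect_identical(moved$W1, fit$params$W1)
  expect_identical(moved$W2, fit$params$W2)
  expect_identical(moved$Wf, fit$params$Wf)
  expect_identical(moved$bf, fit$params$bf)
  expect_equal(dim(moved$Wo), c(100L, 26L))
  expect_equal(attr(moved, "n_classes"), 26L)
  expect_false(identical(moved$Wo[, 1:10], fit$params$Wo))
  # same head seed reproduces the head
  expect_identical(moved$Wo, transfer_network(fit, 26, head_seed = 11)$Wo)
})

test_that("a freshly transferred network scores at chance on letters", {
  tr <- generate_dataset("digits", 60, seed = 1)
  fit <- engram_net(tr, epochs = 2, seed = 3)
  te <- generate_dataset("letters", 260, seed = 5)
  accs <- vapply(1:3, function(s) {
    evaluate_network(transfer_network(fit, 26, head_seed = s), te)$accuracy
  }, 0)
  chance <- 1 / 26
  se <- sqrt(chance * (1 - chance) / (3 * 260))
  expect_lt(mean(accs), chance + 3 * se + 0.04)
})

test_that("train_epoch matches the fitting loop's single-epoch behaviour", {
  tr <- generate_dataset("digits", 30, seed = 2)
  p <- init_network(layer_shapes(), 10, seed = 4)
  r1 <- train_epoch(p, tr, shuffle_seed = 7, mask_seed = 3)
  r2 <- train_epoch(p, tr, shuffle_seed = 7, mask_seed = 3)
  expect_identical(r1$params$W1, r2$params$W1)
  expect_identical(r1$loss, r2$loss)
  expect_false(identical(r1$params$W1,
                         train_epoch(p, tr, shuffle_seed = 8)$params$W1))
})
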