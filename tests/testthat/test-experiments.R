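# Experiment harnesses at smoke scale, plus the bootstrap summary.

smoke_config <- function(experiment, ...) {
  experiment_config(experiment, n_train = 40, n_test = 30, epochs = 2,
                    pretrain_n = if (experiment == "exp3") 40 else NULL,
                    n_replicates = 2, master_seed = 7, ...)
}

test_that("experiment 1 produces its three conditions with complete records", {
  res <- run_experiment1(smoke_config("exp1"))
  expect_setequal(res$conditions,
                  c("control", "dropout-train-50", "dropout-test-50"))
  rec <- res$records
  expect_equal(nrow(rec), 3 * 2 * 2)  # conditions x replicates x epochs
  expect_setequal(unique(rec$condition), res$conditions)
  expect_true(all(rec$test_accuracy >= 0 & rec$test_accuracy <= 1))
  expect_true(all(rec$train_loss >= 0))
  expect_equal(sort(unique(rec$epoch)), 1:2)

  # reproducibility of the full pipeline
  res2 <- run_experiment1(smoke_config("exp1"))
  expect_identical(res$records, res2$records)
})

test_that("experiment 2 sweeps a baseline plus the four dropout rates", {
  res <- run_experiment2(smoke_config("exp2"))
  expect_setequal(res$conditions,
                  c("rate-0", "rate-20", "rate-40", "rate-60", "rate-80"))
  expect_equal(nrow(res$records), 5 * 2 * 2)
})

test_that("experiment 3 runs both transfers and the scratch baseline", {
  res <- run_experiment3(smoke_config("exp3"))
  expect_setequal(res$conditions,
                  c("transfer-with-dropout", "transfer-no-dropout",
                    "scratch"))
  expect_equal(nrow(res$records), 3 * 2 * 2)
  expect_false(anyNA(res$records$test_loss))
})

test_that("conditions within a replicate share data and initialization", {
  # with a zero learning rate and inert dropout phases, control and
  # test-phase conditions stay at the shared initial network, so their
  # training losses coincide exactly
  cfg <- smoke_config("exp1", learning_rate = 0)
  res <- run_experiment1(cfg)
  rec <- res$records
  ctrl <- rec[rec$condition == "control", ]
  dtest <- rec[rec$condition == "dropout-test-50", ]
  expect_identical(ctrl$train_loss, dtest$train_loss)
})

test_that("the bootstrap summary matches direct arithmetic", {
  rec <- data.frame(
    condition = rep(c("a", "b"), each = 6),
    replicate = rep(rep(1:3, each = 2), 2),
    epoch = rep(1:2, 6),
    train_loss = c(0.9, 0.5, 0.8, 0.4, 0.7, 0.3,
                   0.9, 0.6, 0.8, 0.5, 0.7, 0.4),
    test_loss = NA_real_,
    test_accuracy = c(0.1, 0.6, 0.1, 0.7, 0.1, 0.8,
                      0.1, 0.3, 0.1, 0.4, 0.1, 0.5))
  s <- summarize_experiment(rec, n_boot = 200, seed = 1)
  acc_a <- s$table[s$table$condition == "a" &
                     s$table$metric == "test_accuracy", ]
  expect_equal(acc_a$mean, mean(c(0.6, 0.7, 0.8)))
  loss_b <- s$table[s$table$condition == "b" &
                      s$table$metric == "train_loss", ]
  expect_equal(loss_b$mean, mean(c(0.6, 0.5, 0.4)))
  expect_true(all(s$table$lower <= s$table$mean + 1e-12))
  expect_true(all(s$table$upper >= s$table$mean - 1e-12))

  # a clearly separated pair orders with high bootstrap frequency
  ord <- s$orderings[s$orderings$higher == "a" & s$orderings$lower == "b", ]
  expect_gt(ord$frequency, 0.9)

  # determinism and the degenerate single-replicate case
  s2 <- summarize_experiment(rec, n_boot = 200, seed = 1)
  expect_identical(s$table, s2$table)
  one <- summarize_experiment(rec[rec$replicate == 1, ], n_boot = 50,
                              seed = 1)
  acc1 <- one$table[one$table$metric == "test_accuracy", ]
  expect_equal(acc1$lower, acc1$mean)
  expect_equal(acc1$upper, acc1$mean)
  expect_error(summarize_experiment(rec, n_boot = 0), "n_boot")
})

test_that("results round-trip to disk with a verifiable manifest", {
  res <- run_experiment1(smoke_config("exp1"))
  dir <- file.path(tempdir(), "exp1-out")
  write_experiment(res, dir, n_boot = 50)
  expect_true(file.exists(file.path(dir, "records.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(verify_manifest(dir))

  back <- utils::read.csv(file.path(dir, "records.csv"))
  expect_equal(nrow(back), nrow(res$records))
  expect_equal(back$train_loss, res$records$train_loss, tolerance = 1e-12)

  # tampering breaks verification
  cat("x", file = file.path(dir, "records.csv"), append = TRUE)
  expect_error(verify_manifest(dir), "checksum mismatch")
})

test_that("report generation is a pure function of the records CSV", {
  res <- run_experiment1(smoke_config("exp1"))
  dir <- file.path(tempdir(), "exp1-rep")
  write_experiment(res, dir, n_boot = 50)
  out <- file.path(tempdir(), "exp1-figs")
  report_experiment(file.path(dir, "records.csv"), out, zoom = 2,
                    n_boot = 50)
  expect_true(file.exists(file.path(out, "test_accuracy.png")))
  expect_true(file.exists(file.path(out, "train_loss.png")))
  expect_true(file.exists(file.path(out, "final_epoch_summary.csv")))

  empty <- tempfile(fileext = ".csv")
  writeLines("condition,replicate,epoch,train_loss,test_loss,test_accuracy",
             empty)
  expect_error(report_experiment(empty, out), "no rows")
  expect_error(report_experiment(tempfile(), out), "not found")
})
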