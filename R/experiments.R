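#' Configuration of the simulation experiments
#'
#' Builds the run configuration for the three experiments: dropout
#' placement (`"exp1"`), the dropout-rate sweep (`"exp2"`), and transfer
#' learning after head replacement (`"exp3"`).  Each experiment runs
#' `n_replicates` seeded replicates; within a replicate all conditions
#' share the same data, data order, and initialization seeds, so condition
#' differences are attributable to the dropout policy alone.
#'
#' Unset size arguments resolve to the package's scaled defaults, chosen so
#' every condition trains to (near-)convergence on one CPU in minutes (see
#' the methods vignette): 75 epochs with 500/300 synthetic digits for
#' experiment 1 and 450/250 for experiment 2 (which sweeps five
#' conditions), and for experiment 3 a 75-epoch digit pretraining on 500
#' images followed by 75 epochs on 520/260 synthetic letters, with 3
#' replicate seeds.  With `study_scale = TRUE` the original study sizes are
#' used instead (500 epochs; 1,000/1,000 digits; 5,000/1,000 letters).
#'
#' @param experiment `"exp1"`, `"exp2"`, or `"exp3"`.
#' @param n_train,n_test dataset sizes for the experiment's main task.
#' @param epochs training epochs per condition.
#' @param pretrain_n,pretrain_epochs digit pretraining sizes (experiment 3).
#' @param batch_size,learning_rate,loss training hyper-parameters.
#' @param dropout_rate rate for the 50%-dropout conditions (exps 1 and 3).
#' @param rates rate sweep for experiment 2 (a 0% baseline is always
#'   included).
#' @param n_replicates replicate seeds per condition.
#' @param master_seed seed from which all replicate seeds derive.
#' @param data_params a [glyph_gen_params()] for the synthetic generator.
#' @param retrain_dropout logical; in experiment 3, make each transferred
#'   network continue its source network's dropout policy during letter
#'   retraining.  The default `FALSE` retrains both transfers identically
#'   (no dropout), so the comparison isolates the quality of the
#'   transferred "skeleton" features.
#' @param study_scale logical; use the original study's sizes.
#' @param verbose passed to [engram_net()].
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(experiment = c("exp1", "exp2", "exp3"),
                              n_train = NULL, n_test = NULL, epochs = NULL,
                              pretrain_n = NULL, pretrain_epochs = NULL,
                              batch_size = 10L, learning_rate = 0.01,
                              loss = loss_spec(), dropout_rate = 0.5,
                              rates = c(0.2, 0.4, 0.6, 0.8),
                              n_replicates = 3L, master_seed = 1L,
                              data_params = glyph_gen_params(),
                              retrain_dropout = FALSE, study_scale = FALSE,
                              verbose = 0) {
  experiment <- match.arg(experiment)
  if (study_scale) {
    epochs <- epochs %||% 500L
    if (experiment == "exp3") {
      n_train <- n_train %||% 5000L
      n_test <- n_test %||% 1000L
      pretrain_n <- pretrain_n %||% 1000L
    } else {
      n_train <- n_train %||% 1000L
      n_test <- n_test %||% 1000L
    }
  } else {
    if (experiment == "exp3") {
      epochs <- epochs %||% 75L
      n_train <- n_train %||% 520L
      n_test <- n_test %||% 260L
      pretrain_n <- pretrain_n %||% 500L
      pretrain_epochs <- pretrain_epochs %||% 75L
    } else if (experiment == "exp2") {
      epochs <- epochs %||% 75L
      n_train <- n_train %||% 450L
      n_test <- n_test %||% 250L
    } else {
      epochs <- epochs %||% 75L
      n_train <- n_train %||% 500L
      n_test <- n_test %||% 300L
    }
  }
  pretrain_epochs <- pretrain_epochs %||% epochs
  structure(list(
    experiment = experiment,
    n_train = check_count(n_train, "n_train"),
    n_test = check_count(n_test, "n_test"),
    epochs = check_count(epochs, "epochs"),
    pretrain_n = if (experiment == "exp3")
      check_count(pretrain_n %||% 400L, "pretrain_n") else NULL,
    pretrain_epochs = check_count(pretrain_epochs, "pretrain_epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = learning_rate,
    loss = loss,
    dropout_rate = check_fraction(dropout_rate, "dropout_rate",
                                  open_hi = TRUE),
    rates = vapply(rates, check_fraction, 0, name = "rates",
                   open_hi = TRUE),
    n_replicates = check_count(n_replicates, "n_replicates"),
    master_seed = check_count(master_seed, "master_seed", min = 0L),
    data_params = data_params,
    retrain_dropout = isTRUE(retrain_dropout),
    study_scale = isTRUE(study_scale),
    verbose = verbose
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("experiment_config: %s, %d train / %d test, %d epochs, %d replicates (seed %d)\n",
              x$experiment, x$n_train, x$n_test, x$epochs, x$n_replicates,
              x$master_seed))
  invisible(x)
}

# One condition of one replicate; returns per-epoch records.
run_condition <- function(condition, replicate, train, test, policy, config,
                          seed, init_params = NULL, epochs = config$epochs) {
  fit <- engram_net(train, test, dropout = policy, epochs = epochs,
                    batch_size = config$batch_size,
                    learning_rate = config$learning_rate,
                    loss = config$loss, seed = seed,
                    init_params = init_params, verbose = config$verbose)
  list(records = cbind(data.frame(condition = condition,
                                  replicate = replicate),
                       fit$history),
       fit = fit)
}

new_experiment_result <- function(experiment, records, conditions, config) {
  rownames(records) <- NULL
  structure(list(experiment = experiment, records = records,
                 conditions = conditions, config = config),
            class = "engram_experiment")
}

replicate_data <- function(config, classes, r, offset = 0L) {
  train <- generate_dataset(classes, config$n_train, config$data_params,
                            seed = sub_seed(config$master_seed,
                                            1000L + offset + r))
  test <- generate_dataset(classes, config$n_test, config$data_params,
                           seed = sub_seed(config$master_seed,
                                           2000L + offset + r))
  list(train = train, test = test)
}

#' Experiment 1: dropout placement (training vs testing phase)
#'
#' Three conditions per replicate, sharing data and initialization seeds:
#' `control` (no dropout), `dropout-train-50` (50% dropout of the fully
#' connected layer during training, standard inference at test), and
#' `dropout-test-50` (dropout-free training, 50% dropout applied just
#' prior to each evaluation).  Train-phase dropout models stimulation
#' around learning (memory enhancement); test-phase dropout models
#' stimulation during recall (memory disruption).
#'
#' @param config an [experiment_config()] with `experiment = "exp1"`.
#' @return An object of class `"engram_experiment"` with per-epoch records
#'   (`condition`, `replicate`, `epoch`, `train_loss`, `test_accuracy`,
#'   `test_loss`).
#' @seealso [summarize_experiment()], [plot.engram_experiment()],
#'   [write_experiment()]
#' @export
run_experiment1 <- function(config = experiment_config("exp1")) {
  stopifnot(inherits(config, "experiment_config"))
  rate <- config$dropout_rate
  lab <- sprintf("%.0f", 100 * rate)
  conditions <- c("control", paste0("dropout-train-", lab),
                  paste0("dropout-test-", lab))
  policies <- list(dropout_policy("none"),
                   dropout_policy("train", rate),
                   dropout_policy("test", rate))
  rec <- list()
  for (r in seq_len(config$n_replicates)) {
    d <- replicate_data(config, "digits", r)
    seed <- sub_seed(config$master_seed, 3000L + r)
    for (i in seq_along(conditions)) {
      rec[[length(rec) + 1L]] <-
        run_condition(conditions[i], r, d$train, d$test, policies[[i]],
                      config, seed)$records
    }
  }
  new_experiment_result("exp1", do.call(rbind, rec), conditions, config)
}

#' Experiment 2: dropout-rate sweep during training
#'
#' A 0% baseline plus train-phase dropout at each rate in `config$rates`
#' (20/40/60/80% by default), all sharing data and initialization seeds
#' within a replicate.
#'
#' @inheritParams run_experiment1
#' @return An `"engram_experiment"` object.
#' @export
run_experiment2 <- function(config = experiment_config("exp2")) {
  stopifnot(inherits(config, "experiment_config"))
  rates <- c(0, config$rates)
  conditions <- sprintf("rate-%.0f", 100 * rates)
  rec <- list()
  for (r in seq_len(config$n_replicates)) {
    d <- replicate_data(config, "digits", r)
    seed <- sub_seed(config$master_seed, 3000L + r)
    for (i in seq_along(rates)) {
      pol <- if (rates[i] == 0) dropout_policy("none")
             else dropout_policy("train", rates[i])
      rec[[length(rec) + 1L]] <-
        run_condition(conditions[i], r, d$train, d$test, pol, config,
                      seed)$records
    }
  }
  new_experiment_result("exp2", do.call(rbind, rec), conditions, config)
}

#' Experiment 3: transfer learning as a model of chronic stimulation
#'
#' Per replicate: two networks are pretrained on digits (with and without
#' 50% train-phase dropout), their output heads are stripped and replaced
#' for the 26 uppercase-letter classes ([transfer_network()]), and both
#' are retrained on letters alongside a scratch-trained baseline.  By
#' default both transfers retrain without dropout, so the conditions
#' compare the transferred feature bodies under identical retraining;
#' `retrain_dropout = TRUE` instead lets each transfer continue its source
#' network's policy.  The scratch baseline always trains without dropout.
#'
#' @inheritParams run_experiment1
#' @return An `"engram_experiment"` object with conditions
#'   `transfer-with-dropout`, `transfer-no-dropout`, `scratch`.
#' @export
run_experiment3 <- function(config = experiment_config("exp3")) {
  stopifnot(inherits(config, "experiment_config"))
  rate <- config$dropout_rate
  conditions <- c("transfer-with-dropout", "transfer-no-dropout", "scratch")
  pre_config <- config
  pre_config$n_train <- config$pretrain_n
  rec <- list()
  for (r in seq_len(config$n_replicates)) {
    digits <- generate_dataset("digits", config$pretrain_n,
                               config$data_params,
                               seed = sub_seed(config$master_seed, 5000L + r))
    pre_seed <- sub_seed(config$master_seed, 6000L + r)
    pre_drop <- engram_net(digits, dropout = dropout_policy("train", rate),
                           epochs = config$pretrain_epochs,
                           batch_size = config$batch_size,
                           learning_rate = config$learning_rate,
                           loss = config$loss, seed = pre_seed,
                           verbose = config$verbose)
    pre_ctrl <- engram_net(digits, dropout = dropout_policy("none"),
                           epochs = config$pretrain_epochs,
                           batch_size = config$batch_size,
                           learning_rate = config$learning_rate,
                           loss = config$loss, seed = pre_seed,
                           verbose = config$verbose)

    d <- replicate_data(config, "letters", r, offset = 500L)
    head_seed <- sub_seed(config$master_seed, 7000L + r)
    seed <- sub_seed(config$master_seed, 8000L + r)
    n_letters <- d$train$n_classes

    setups <- list(
      list(cond = "transfer-with-dropout",
           init = transfer_network(pre_drop, n_letters, head_seed),
           pol = if (config$retrain_dropout) dropout_policy("train", rate)
                 else dropout_policy("none")),
      list(cond = "transfer-no-dropout",
           init = transfer_network(pre_ctrl, n_letters, head_seed),
           pol = dropout_policy("none")),
      list(cond = "scratch", init = NULL, pol = dropout_policy("none"))
    )
    for (s in setups) {
      rec[[length(rec) + 1L]] <-
        run_condition(s$cond, r, d$train, d$test, s$pol, config, seed,
                      init_params = s$init)$records
    }
  }
  new_experiment_result("exp3", do.call(rbind, rec), conditions, config)
}

#' @export
print.engram_experiment <- function(x, ...) {
  cat(sprintf("engram_experiment %s: %d conditions x %d replicates x %d epochs\n",
              x$experiment, length(x$conditions),
              max(x$records$replicate), max(x$records$epoch)))
  fin <- final_epoch_records(x)
  agg <- stats::aggregate(test_accuracy ~ condition, fin, mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-22s mean final accuracy %.3f\n",
                agg$condition[i], agg$test_accuracy[i]))
  invisible(x)
}

final_epoch_records <- function(x) {
  records <- if (inherits(x, "engram_experiment")) x$records else x
  records[records$epoch == max(records$epoch), , drop = FALSE]
}

#' Summarize an experiment: final-epoch means, bootstrap intervals, orderings
#'
#' For each condition, the mean over replicates of the final-epoch test
#' accuracy, training loss, and test loss, with percentile bootstrap
#' intervals (resampling replicates).  Additionally, for every condition
#' pair, the bootstrap frequency with which the first condition's mean
#' final accuracy exceeds the second's.
#'
#' @param result an `"engram_experiment"` or its records data frame.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed RNG seed for the bootstrap.
#' @param level interval coverage.
#' @return list with `table` (one row per condition x metric) and
#'   `orderings` (condition pairs with ordering frequency), both data
#'   frames.
#' @export
summarize_experiment <- function(result, n_boot = 1000L, seed = 1L,
                                 level = 0.95) {
  n_boot <- check_count(n_boot, "n_boot")
  fin <- final_epoch_records(result)
  conds <- unique(fin$condition)
  metrics <- c("test_accuracy", "train_loss", "test_loss")
  metrics <- metrics[vapply(metrics, function(m) any(!is.na(fin[[m]])), TRUE)]
  alpha <- (1 - level) / 2

  rows <- list()
  boot_means <- list()
  with_seed(seed, {
    for (cond in conds) {
      sub <- fin[fin$condition == cond, , drop = FALSE]
      nr <- nrow(sub)
      bidx <- matrix(sample.int(nr, nr * n_boot, replace = TRUE), nr, n_boot)
      for (m in metrics) {
        v <- sub[[m]]
        bm <- colMeans(matrix(v[bidx], nr, n_boot))
        if (m == "test_accuracy") boot_means[[cond]] <- bm
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, metric = m, mean = mean(v),
          lower = if (nr > 1) stats::quantile(bm, alpha, names = FALSE)
                  else mean(v),
          upper = if (nr > 1) stats::quantile(bm, 1 - alpha, names = FALSE)
                  else mean(v),
          n_replicates = nr)
      }
    }
  })
  tab <- do.call(rbind, rows)

  ords <- list()
  if (length(conds) > 1L && "test_accuracy" %in% metrics) {
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (i == j) next
      ords[[length(ords) + 1L]] <- data.frame(
        higher = conds[i], lower = conds[j],
        frequency = mean(boot_means[[conds[i]]] > boot_means[[conds[j]]]))
    }
  }
  list(table = tab,
       orderings = if (length(ords)) do.call(rbind, ords) else NULL)
}

#' @export
summary.engram_experiment <- function(object, n_boot = 1000L, seed = 1L,
                                      ...) {
  out <- summarize_experiment(object, n_boot = n_boot, seed = seed)
  out$experiment <- object$experiment
  class(out) <- "summary.engram_experiment"
  out
}

#' @export
print.summary.engram_experiment <- function(x, ...) {
  cat(sprintf("Summary of %s (final epoch, mean over replicates, bootstrap CI)\n",
              x$experiment %||% "experiment"))
  tab <- x$table
  tab$mean <- round(tab$mean, 4)
  tab$lower <- round(tab$lower, 4)
  tab$upper <- round(tab$upper, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
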