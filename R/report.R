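#' Write experiment results to disk
#'
#' Emits `records.csv` (columns `condition`, `replicate`, `epoch`,
#' `train_loss`, `test_loss`, `test_accuracy`), `summary.json` (the
#' [summarize_experiment()] output), and `manifest.json` — a run manifest
#' holding the configuration snapshot, package version, master seed, and an
#' MD5-checksummed inventory of every output file, from which a run is
#' fully reconstructible.
#'
#' @param result an `"engram_experiment"`.
#' @param dir output directory (created if missing).
#' @param n_boot,seed bootstrap settings for the summary.
#' @return Invisibly, the manifest as a list.
#' @export
write_experiment <- function(result, dir, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(result, "engram_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- result$records[, c("condition", "replicate", "epoch", "train_loss",
                            "test_loss", "test_accuracy")]
  csv_path <- file.path(dir, "records.csv")
  utils::write.csv(rec, csv_path, row.names = FALSE)

  summ <- summarize_experiment(result, n_boot = n_boot, seed = seed)
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, json_path, dataframe = "rows", digits = NA,
                       pretty = TRUE, auto_unbox = TRUE)

  files <- c("records.csv", "summary.json")
  manifest <- list(
    experiment = result$experiment,
    package = "engramnet",
    version = as.character(utils::packageVersion("engramnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_snapshot(result$config),
    conditions = result$conditions,
    files = lapply(files, function(f) {
      list(name = f,
           md5 = unname(tools::md5sum(file.path(dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

config_snapshot <- function(config) {
  s <- unclass(config)
  s$loss <- unclass(s$loss)
  s$data_params <- unclass(s$data_params)
  s
}

#' Verify a run manifest
#'
#' Checks that every file listed in a `manifest.json` exists and matches
#' its recorded MD5 checksum.
#'
#' @param dir directory holding `manifest.json`.
#' @return `TRUE` invisibly, or an error naming the first mismatch.
#' @export
verify_manifest <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  for (f in mf$files) {
    path <- file.path(dir, f$name)
    if (!file.exists(path)) stop_bad("manifest file missing: '%s'", f$name)
    if (!identical(unname(tools::md5sum(path)), f$md5))
      stop_bad("checksum mismatch for '%s'", f$name)
  }
  invisible(TRUE)
}

read_records_csv <- function(path) {
  if (!file.exists(path)) stop_bad("results file not found: '%s'", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("condition", "replicate", "epoch", "train_loss",
              "test_accuracy")
  missing <- setdiff(needed, names(rec))
  if (length(missing))
    stop_bad("malformed results CSV '%s': missing column(s) %s", path,
             paste(missing, collapse = ", "))
  if (!nrow(rec)) stop_bad("results CSV '%s' has no rows", path)
  bad <- which(!is.finite(rec$epoch))
  if (length(bad))
    stop_bad("malformed results CSV '%s': non-numeric epoch at row %d",
             path, bad[1L])
  rec
}

# Mean curve (and replicate range) per condition for one metric.
condition_curves <- function(records, metric) {
  agg <- stats::aggregate(records[[metric]],
                          by = list(condition = records$condition,
                                    epoch = records$epoch),
                          FUN = function(v) c(mean = mean(v), lo = min(v),
                                              hi = max(v)))
  data.frame(condition = agg$condition, epoch = agg$epoch,
             mean = agg$x[, "mean"], lo = agg$x[, "lo"], hi = agg$x[, "hi"])
}

plot_metric_curves <- function(records, metric, main = metric,
                               epochs = NULL, legend_pos = "bottomright") {
  rec <- records[!is.na(records[[metric]]), , drop = FALSE]
  if (!nrow(rec)) return(invisible(NULL))
  if (!is.null(epochs)) rec <- rec[rec$epoch <= epochs, , drop = FALSE]
  cur <- condition_curves(rec, metric)
  conds <- unique(cur$condition)
  cols <- grDevices::hcl.colors(max(3L, length(conds)), "Dark 3")
  graphics::plot(NA, xlim = range(cur$epoch), ylim = range(cur$lo, cur$hi),
                 xlab = "epoch", ylab = gsub("_", " ", metric), main = main)
  for (i in seq_along(conds)) {
    sub <- cur[cur$condition == conds[i], ]
    sub <- sub[order(sub$epoch), ]
    graphics::polygon(c(sub$epoch, rev(sub$epoch)), c(sub$lo, rev(sub$hi)),
                      col = grDevices::adjustcolor(cols[i], 0.15),
                      border = NA)
    graphics::lines(sub$epoch, sub$mean, col = cols[i], lwd = 2)
  }
  graphics::legend(legend_pos, legend = conds, col = cols[seq_along(conds)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(cur)
}

#' Plot learning curves of an experiment
#'
#' Mean curve per condition across replicates, with the replicate range as
#' a shaded band.
#'
#' @param x an `"engram_experiment"` or a records data frame.
#' @param metric which metric to draw.
#' @param zoom optional epoch cutoff for an additional zoomed panel (e.g.
#'   the first 20 epochs of the training-loss curves).
#' @param ... ignored.
#' @export
plot.engram_experiment <- function(x, metric = c("test_accuracy",
                                                 "train_loss", "test_loss"),
                                   zoom = NULL, ...) {
  metric <- match.arg(metric)
  records <- if (inherits(x, "engram_experiment")) x$records else x
  if (!is.null(zoom)) {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
  }
  pos <- if (metric == "test_accuracy") "bottomright" else "topright"
  plot_metric_curves(records, metric, legend_pos = pos)
  if (!is.null(zoom))
    plot_metric_curves(records, metric, epochs = zoom,
                       main = sprintf("%s (first %d epochs)", metric, zoom),
                       legend_pos = pos)
  invisible(x)
}

#' Render figures and a summary from a results CSV
#'
#' A pure function of the records CSV (training is never recomputed):
#' writes accuracy and loss curve figures per condition and a final-epoch
#' summary table.
#'
#' @param csv_path path to a `records.csv` written by [write_experiment()].
#' @param dir output directory.
#' @param zoom optional epoch cutoff for a zoomed training-loss panel.
#' @param n_boot,seed bootstrap settings.
#' @return Invisibly, the paths written.
#' @export
report_experiment <- function(csv_path, dir, zoom = NULL, n_boot = 1000L,
                              seed = 1L) {
  rec <- read_records_csv(csv_path)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (metric in c("test_accuracy", "train_loss", "test_loss")) {
    if (all(is.na(rec[[metric]] %||% NA))) next
    p <- file.path(dir, paste0(metric, ".png"))
    grDevices::png(p, width = if (is.null(zoom)) 800 else 1400, height = 600,
                   res = 110)
    plot.engram_experiment(rec, metric = metric,
                           zoom = if (metric == "train_loss") zoom else NULL)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  summ <- summarize_experiment(rec, n_boot = n_boot, seed = seed)
  sp <- file.path(dir, "final_epoch_summary.csv")
  utils::write.csv(summ$table, sp, row.names = FALSE)
  invisible(c(paths, sp))
}
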