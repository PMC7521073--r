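# Shared fixtures: tiny network geometries, a nearest-centroid oracle, and
# a cache so the full-scale experiment runs are computed once per session.

tiny_shapes <- function(fc = 5L) {
  layer_shapes(input_size = 6, kernel = 2, filters = c(2, 2), pool = FALSE,
               fc_units = fc)
}

tiny_batch <- function(n = 2L, size = 6L, n_classes = 3L, seed = 9L) {
  set.seed(seed)
  list(images = array(runif(size * size * n), c(size, size, n)),
       labels = sample(0:(n_classes - 1L), n, replace = TRUE))
}

# Nearest-centroid classifier: the independent learnability oracle for the
# synthetic data (train per-class mean images, assign by minimum distance).
centroid_accuracy <- function(train, test) {
  classes <- sort(unique(train$labels))
  centroids <- vapply(classes, function(cl) {
    rowMeans(matrix(train$images[, , train$labels == cl], nrow = 28 * 28))
  }, numeric(28 * 28))
  xs <- matrix(test$images, nrow = 28 * 28)
  pred <- apply(xs, 2, function(v) {
    classes[which.min(colSums((centroids - v)^2))]
  })
  mean(pred == test$labels)
}

# Full-scale experiment results, shared across acceptance checks.
.experiment_cache <- new.env(parent = emptyenv())

cached_experiment <- function(id) {
  if (is.null(.experiment_cache[[id]])) {
    .experiment_cache[[id]] <- switch(id,
      exp1 = run_experiment1(),
      exp2 = run_experiment2(),
      exp3 = run_experiment3(),
      stop("unknown experiment id"))
  }
  .experiment_cache[[id]]
}

# Mean final-epoch value of a metric per condition, as a named vector.
final_means <- function(result, metric = "test_accuracy") {
  rec <- result$records
  fin <- rec[rec$epoch == max(rec$epoch), ]
  out <- tapply(fin[[metric]], fin$condition, mean)
  out[!is.na(out)]
}
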