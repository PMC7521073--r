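#' Dropout policy: where and how engram nodes are silenced
#'
#' Dropout models neurostimulation as the random silencing of engram nodes,
#' here the units of the fully connected layer.  The policy says in which
#' phase masks are applied: `"train"` (masks during learning only — the
#' enhancement regime), `"test"` (training is dropout-free, masks are
#' applied just prior to each evaluation — the disruption regime), or
#' `"none"` (the operator is the identity and the engine is mask-free).
#'
#' @param phase one of `"none"`, `"train"`, `"test"`.
#' @param rate fraction of units dropped, in `[0, 1)`.  A rate of 1 would
#'   silence the whole layer and break the inverted scaling, so it is
#'   rejected.
#' @param rescale logical; rescale kept units by `1 / (1 - rate)` (inverted
#'   dropout, preserving the expected activation).  The same operator is
#'   used in both phases.
#' @param per_sample logical; draw one mask per sample instead of one per
#'   batch (optimization/evaluation step).
#' @return An object of class `"dropout_policy"`.
#' @examples
#' dropout_policy("train", 0.5)
#' dropout_policy("none")
#' @export
dropout_policy <- function(phase = c("none", "train", "test"), rate = 0,
                           rescale = TRUE, per_sample = FALSE) {
  phase <- match.arg(phase)
  rate <- check_fraction(rate, "rate", open_hi = TRUE)
  if (phase == "none") rate <- 0
  structure(list(phase = phase, rate = rate, rescale = isTRUE(rescale),
                 per_sample = isTRUE(per_sample), target_layer = "fc"),
            class = "dropout_policy")
}

#' @export
print.dropout_policy <- function(x, ...) {
  if (x$phase == "none") {
    cat("dropout policy: none (identity)\n")
  } else {
    cat(sprintf(
      "dropout policy: %.0f%% of fully connected units, %s phase%s%s\n",
      100 * x$rate, x$phase,
      if (x$rescale) ", inverted scaling" else ", no rescaling",
      if (x$per_sample) ", per-sample masks" else ""))
  }
  invisible(x)
}

#' Sample a Bernoulli keep/drop mask
#'
#' Each unit is dropped independently with probability `rate`, using the
#' current R RNG state (seed with `set.seed()` for determinism).
#'
#' @param width number of units in the target layer.
#' @param rate drop probability in `[0, 1)`.
#' @return An object of class `"dropout_mask"`: list with `keep` (0/1
#'   integer vector of length `width`) and `realized_drop_fraction`.
#' @examples
#' set.seed(1)
#' m <- sample_mask(100, 0.5)
#' m$realized_drop_fraction
#' @export
sample_mask <- function(width, rate) {
  width <- check_count(width, "width")
  rate <- check_fraction(rate, "rate", open_hi = TRUE)
  keep <- as.integer(stats::runif(width) >= rate)
  structure(list(keep = keep,
                 realized_drop_fraction = 1 - mean(keep)),
            class = "dropout_mask")
}

#' Apply a dropout mask to a vector of activations
#'
#' Dropped units become exactly zero; kept units are scaled by
#' `1 / (1 - rate)` (inverted dropout) so that the expected output equals
#' the input under the Bernoulli mask model.
#'
#' @param activations numeric vector.
#' @param mask a [sample_mask()] result or a 0/1 vector of the same length.
#' @param rate the drop rate the mask was sampled at.
#' @param rescale logical; set `FALSE` to silence without rescaling.
#' @return Numeric vector of masked activations.
#' @examples
#' apply_dropout(c(2, 4, 6, 8), c(1, 0, 1, 0), rate = 0.5)  # 4 0 12 0
#' @export
apply_dropout <- function(activations, mask, rate, rescale = TRUE) {
  keep <- if (inherits(mask, "dropout_mask")) mask$keep else mask
  if (length(keep) != length(activations))
    stop_bad("mask length (%d) does not match activations (%d)",
             length(keep), length(activations))
  rate <- check_fraction(rate, "rate", open_hi = TRUE)
  scale <- if (isTRUE(rescale)) 1 / (1 - rate) else 1
  as.numeric(activations) * keep * scale
}

# Internal: matrix of masks (fc x n), one column per optimization /
# evaluation step (or per sample), drawn from the current RNG state.
mask_matrix <- function(width, rate, n) {
  matrix(as.numeric(stats::runif(width * n) >= rate), nrow = width, ncol = n)
}
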