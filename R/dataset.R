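#' Labeled glyph image dataset
#'
#' The common container for synthetic and IDX-loaded data: a batch of
#' 28x28 single-channel images in `[0, 1]` with 0-based integer class
#' labels and the class inventory.
#'
#' @param images numeric array `(28, 28, n)` or `(28, 28, 1, n)` with
#'   values in `[0, 1]`.
#' @param labels integer vector of 0-based class indices, one per image;
#'   every label must be `< length(class_names)`.
#' @param class_names character vector of glyph identifiers.
#' @param provenance free-form list recording how the data were produced
#'   (e.g. generator seed and parameters, or IDX file paths).
#' @return An object of class `"glyph_dataset"` with elements `images`
#'   (`(28, 28, n)` array), `labels`, `class_names`, `n_classes`,
#'   `provenance`.
#' @seealso [generate_dataset()], [load_idx()]
#' @export
glyph_dataset <- function(images, labels, class_names,
                          provenance = list(source = "unknown")) {
  images <- as_image_cube(images, NULL)
  labels <- as.integer(labels)
  n <- dim(images)[3L]
  if (length(labels) != n)
    stop_bad("%d labels for %d images", length(labels), n)
  if (anyNA(images) || min(images) < 0 || max(images) > 1)
    stop_bad("image values must lie in [0, 1] with no missing values")
  if (any(labels < 0L) || any(labels >= length(class_names)))
    stop_bad("labels must be 0-based indices below %d", length(class_names))
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names),
                 n_classes = length(class_names),
                 provenance = provenance),
            class = "glyph_dataset")
}

#' @export
print.glyph_dataset <- function(x, ...) {
  cat(sprintf("glyph_dataset: %d images (28x28), %d classes [%s%s]\n",
              length(x$labels), x$n_classes,
              paste(utils::head(x$class_names, 6), collapse = ""),
              if (x$n_classes > 6) "..." else ""))
  cat(sprintf("  source: %s\n", x$provenance$source %||% "unknown"))
  invisible(x)
}

#' @export
length.glyph_dataset <- function(x) length(x$labels)

#' Subset a glyph dataset
#' @param x a [glyph_dataset()].
#' @param i index vector of images to keep.
#' @param ... ignored.
#' @export
`[.glyph_dataset` <- function(x, i, ...) {
  glyph_dataset(x$images[, , i, drop = FALSE], x$labels[i], x$class_names,
                x$provenance)
}

#' @export
plot.glyph_dataset <- function(x, n = 16, ...) {
  n <- min(n, length(x$labels))
  side <- ceiling(sqrt(n))
  op <- graphics::par(mfrow = c(side, side), mar = c(0.5, 0.5, 1.2, 0.5))
  on.exit(graphics::par(op))
  for (i in seq_len(n)) {
    img <- x$images[, , i]
    graphics::image(t(img[nrow(img):1, ]), col = grey.colors(64, 0, 1),
                    axes = FALSE, main = x$class_names[x$labels[i] + 1L],
                    cex.main = 0.8)
  }
  invisible(x)
}

#' Generate a synthetic glyph dataset
#'
#' Produces an EMNIST-like labeled dataset: balanced class assignment
#' (per-class counts differ by at most one) over the requested inventory,
#' each image rendered by [generate_glyph()] with seeded variability.  The
#' result is a pure function of `(classes, n, params, seed)`; disjoint
#' train/test sets are obtained by distinct seeds.
#'
#' @param classes `"digits"` (0-9), `"letters"` (A-Z), `"all"`, or a
#'   character vector of glyph identifiers.
#' @param n number of images; must be at least the number of classes when
#'   `balanced`.
#' @param params a [glyph_gen_params()].
#' @param seed integer seed.
#' @param balanced logical; if `FALSE`, classes are sampled uniformly at
#'   random instead of in balanced counts.
#' @return A [glyph_dataset()].
#' @examples
#' d <- generate_dataset("digits", n = 20, seed = 1)
#' table(d$labels)
#' @export
generate_dataset <- function(classes = "digits", n, params = glyph_gen_params(),
                             seed = 1L, balanced = TRUE) {
  if (length(classes) == 1L && classes %in% c("digits", "letters", "all")) {
    class_names <- glyph_class_names(classes)
  } else {
    class_names <- as.character(classes)
    if (!all(class_names %in% glyph_class_names("all")))
      stop_bad("unknown glyph classes: %s",
               paste(setdiff(class_names, glyph_class_names("all")),
                     collapse = ", "))
  }
  n <- check_count(n, "n")
  seed <- check_count(seed, "seed", min = 0L)
  k <- length(class_names)
  if (balanced && n < k)
    stop_bad("balanced dataset needs n >= %d (one per class), got %d", k, n)

  with_seed(seed, {
    if (balanced) {
      base <- n %/% k
      extra <- n %% k
      counts <- rep(base, k) + (seq_len(k) <= extra)
      labels <- sample(rep.int(seq_len(k) - 1L, counts))
    } else {
      labels <- sample(seq_len(k) - 1L, n, replace = TRUE)
    }
    images <- array(0, dim = c(28L, 28L, n))
    for (i in seq_len(n)) {
      images[, , i] <- generate_glyph(class_names[labels[i] + 1L], params)
    }
    glyph_dataset(images, labels, class_names,
                  provenance = list(source = "synthetic", seed = seed,
                                    params = unclass(params),
                                    balanced = balanced))
  })
}
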