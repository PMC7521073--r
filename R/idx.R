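# IDX binary format (big-endian), the distribution format of the MNIST /
# EMNIST family: magic 0x00000803 for 3-D uint8 image tensors, 0x00000801
# for 1-D uint8 label vectors.  Files may be gzip-compressed (.gz).

IDX_MAGIC_IMAGES <- 2051L  # 0x00000803
IDX_MAGIC_LABELS <- 2049L  # 0x00000801

idx_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_idx_header <- function(con, path, expected_magic, n_dims) {
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(magic) != 1L || magic != expected_magic)
    stop_bad("'%s' is not a valid IDX file (magic %s, expected %d)",
             path, if (length(magic)) magic else "missing", expected_magic)
  dims <- readBin(con, "integer", n_dims, size = 4, endian = "big")
  if (length(dims) != n_dims || any(dims <= 0))
    stop_bad("'%s' has a truncated or invalid IDX header", path)
  dims
}

#' Read an EMNIST/MNIST-style IDX image/label file pair
#'
#' Parses the big-endian IDX container (optionally gzip-compressed),
#' rescales pixel bytes to `[0, 1]`, and by default transposes each image:
#' the EMNIST distribution stores images transposed relative to the usual
#' visual orientation.  Orientation does not affect learning, only
#' visualization.
#'
#' @param images_path path to the images file (IDX magic `0x00000803`).
#' @param labels_path path to the labels file (IDX magic `0x00000801`).
#' @param class_names optional class inventory; defaults to generic names
#'   covering the label range.
#' @param transpose logical; apply the EMNIST transpose convention.
#' @return A [glyph_dataset()].
#' @seealso [write_idx()] for the inverse operation.
#' @export
load_idx <- function(images_path, labels_path, class_names = NULL,
                     transpose = TRUE) {
  for (p in c(images_path, labels_path))
    if (!file.exists(p)) stop_bad("file not found: '%s'", p)

  con <- idx_connection(images_path, "rb")
  on.exit(close(con), add = TRUE)
  dims <- read_idx_header(con, images_path, IDX_MAGIC_IMAGES, 3L)
  n <- dims[1L]; h <- dims[2L]; w <- dims[3L]
  raw_px <- readBin(con, "raw", n * h * w)
  if (length(raw_px) != n * h * w)
    stop_bad("'%s': truncated payload (%d of %d pixel bytes)",
             images_path, length(raw_px), n * h * w)

  con2 <- idx_connection(labels_path, "rb")
  on.exit(close(con2), add = TRUE)
  nlab <- read_idx_header(con2, labels_path, IDX_MAGIC_LABELS, 1L)
  raw_lab <- readBin(con2, "raw", nlab)
  if (length(raw_lab) != nlab)
    stop_bad("'%s': truncated payload (%d of %d labels)",
             labels_path, length(raw_lab), nlab)
  if (nlab != n)
    stop_bad("label count (%d) in '%s' does not match image count (%d) in '%s'",
             nlab, labels_path, n, images_path)

  px <- as.integer(raw_px) / 255
  # IDX stores each image row-major; R arrays are column-major, so filling
  # (w, h, n) puts pixels at [col, row] -- i.e. the transposed image.
  imgs <- array(px, dim = c(w, h, n))
  if (!transpose) imgs <- aperm(imgs, c(2L, 1L, 3L))
  labels <- as.integer(raw_lab)
  if (is.null(class_names))
    class_names <- as.character(seq_len(max(labels) + 1L) - 1L)
  glyph_dataset(imgs, labels, class_names,
                provenance = list(source = "idx", images = images_path,
                                  labels = labels_path,
                                  transpose = transpose))
}

#' Write a glyph dataset as an IDX image/label file pair
#'
#' Pixels are quantized to bytes (`round(255 * value)`).  With
#' `transpose = TRUE` (default) images are stored in the EMNIST
#' orientation so that [load_idx()] with its defaults round-trips.
#'
#' @param dataset a [glyph_dataset()].
#' @param images_path,labels_path output paths; a `.gz` suffix writes
#'   gzip-compressed files.
#' @param transpose logical; store in the EMNIST transposed orientation.
#' @return Invisibly, the two paths.
#' @export
write_idx <- function(dataset, images_path, labels_path, transpose = TRUE) {
  stopifnot(inherits(dataset, "glyph_dataset"))
  imgs <- dataset$images
  n <- dim(imgs)[3L]
  # IDX payloads are row-major per image.  Writing the column-major R array
  # as-is emits visual columns as stored rows, i.e. the EMNIST transposed
  # orientation; for an untransposed file swap the spatial axes first.
  if (!transpose) imgs <- aperm(imgs, c(2L, 1L, 3L))
  con <- idx_connection(images_path, "wb")
  writeBin(IDX_MAGIC_IMAGES, con, size = 4, endian = "big")
  writeBin(c(n, dim(imgs)[2L], dim(imgs)[1L]), con, size = 4, endian = "big")
  writeBin(as.raw(round(pmin(pmax(imgs, 0), 1) * 255)), con)
  close(con)
  con <- idx_connection(labels_path, "wb")
  writeBin(IDX_MAGIC_LABELS, con, size = 4, endian = "big")
  writeBin(n, con, size = 4, endian = "big")
  writeBin(as.raw(dataset$labels), con)
  close(con)
  invisible(c(images = images_path, labels = labels_path))
}
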