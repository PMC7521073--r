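# Synthetic glyph rendering: each class (digits 0-9, uppercase A-Z) has a
# fixed stroke skeleton (polylines and elliptical arcs) on the unit square.
# Images are produced by rasterizing the skeleton at a sampled stroke width
# after a random affine jitter, then adding blur and pixel noise -- a
# dependency-free stand-in for natural handwriting variability.

# Points along an elliptical arc, angles in degrees, y up.
arc_pts <- function(cx, cy, rx, ry, from, to, n = 16L) {
  a <- seq(from, to, length.out = n) * pi / 180
  cbind(cx + rx * cos(a), cy + ry * sin(a))
}

seg <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  m
}

# Stroke skeletons in [0,1]^2, y pointing up.
glyph_prototypes <- local({
  p <- list()
  p[["0"]] <- list(arc_pts(.5, .5, .30, .44, 0, 360))
  p[["1"]] <- list(seg(.35, .75, .52, .95, .52, .05))
  p[["2"]] <- list(rbind(arc_pts(.5, .74, .27, .20, 160, -20),
                         seg(.24, .05)),
                   seg(.24, .05, .78, .05))
  p[["3"]] <- list(arc_pts(.5, .73, .25, .22, 140, -90),
                   arc_pts(.5, .27, .25, .22, 90, -140))
  p[["4"]] <- list(seg(.68, .05, .68, .95, .20, .32), seg(.20, .32, .85, .32))
  p[["5"]] <- list(seg(.75, .95, .28, .95, .28, .58),
                   arc_pts(.47, .33, .28, .27, 110, -120))
  p[["6"]] <- list(arc_pts(.60, .60, .33, .36, 60, 200),
                   arc_pts(.50, .28, .25, .23, 0, 360))
  p[["7"]] <- list(seg(.22, .95, .80, .95, .42, .05))
  p[["8"]] <- list(arc_pts(.5, .71, .23, .22, 0, 360),
                   arc_pts(.5, .26, .27, .23, 0, 360))
  p[["9"]] <- list(arc_pts(.5, .70, .24, .22, 0, 360),
                   seg(.74, .70, .60, .05))
  p[["A"]] <- list(seg(.15, .05, .50, .95, .85, .05), seg(.30, .42, .70, .42))
  p[["B"]] <- list(seg(.22, .05, .22, .95),
                   arc_pts(.22, .725, .45, .225, 90, -90),
                   arc_pts(.22, .275, .52, .225, 90, -90))
  p[["C"]] <- list(arc_pts(.55, .5, .33, .44, 45, 315))
  p[["D"]] <- list(seg(.22, .05, .22, .95), arc_pts(.22, .5, .55, .45, 90, -90))
  p[["E"]] <- list(seg(.78, .95, .22, .95, .22, .05, .78, .05),
                   seg(.22, .50, .68, .50))
  p[["F"]] <- list(seg(.78, .95, .22, .95, .22, .05), seg(.22, .52, .66, .52))
  p[["G"]] <- list(arc_pts(.55, .5, .33, .44, 40, 320), seg(.88, .42, .58, .42))
  p[["H"]] <- list(seg(.2, .05, .2, .95), seg(.8, .05, .8, .95),
                   seg(.2, .5, .8, .5))
  p[["I"]] <- list(seg(.5, .05, .5, .95), seg(.3, .95, .7, .95),
                   seg(.3, .05, .7, .05))
  p[["J"]] <- list(seg(.66, .95, .66, .28), arc_pts(.47, .28, .19, .23, 0, -180))
  p[["K"]] <- list(seg(.22, .05, .22, .95), seg(.22, .45, .80, .95),
                   seg(.22, .45, .80, .05))
  p[["L"]] <- list(seg(.25, .95, .25, .05, .80, .05))
  p[["M"]] <- list(seg(.14, .05, .14, .95, .50, .42, .86, .95, .86, .05))
  p[["N"]] <- list(seg(.2, .05, .2, .95, .8, .05, .8, .95))
  p[["O"]] <- list(arc_pts(.5, .5, .32, .44, 0, 360))
  p[["P"]] <- list(seg(.22, .05, .22, .95), arc_pts(.22, .71, .50, .24, 90, -90))
  p[["Q"]] <- list(arc_pts(.5, .5, .32, .44, 0, 360), seg(.58, .30, .85, .04))
  p[["R"]] <- list(seg(.22, .05, .22, .95),
                   arc_pts(.22, .71, .50, .24, 90, -90),
                   seg(.35, .48, .80, .05))
  p[["S"]] <- list(rbind(arc_pts(.5, .72, .26, .22, 40, 250),
                         arc_pts(.5, .28, .26, .22, 110, -110)))
  p[["T"]] <- list(seg(.2, .95, .8, .95), seg(.5, .95, .5, .05))
  p[["U"]] <- list(rbind(seg(.2, .95, .2, .35), arc_pts(.5, .35, .30, .30, 180, 360),
                         seg(.8, .35, .8, .95)))
  p[["V"]] <- list(seg(.18, .95, .50, .05, .82, .95))
  p[["W"]] <- list(seg(.10, .95, .30, .05, .50, .60, .70, .05, .90, .95))
  p[["X"]] <- list(seg(.2, .95, .8, .05), seg(.8, .95, .2, .05))
  p[["Y"]] <- list(seg(.2, .95, .5, .50), seg(.8, .95, .5, .50),
                   seg(.5, .50, .5, .05))
  p[["Z"]] <- list(seg(.2, .95, .8, .95, .2, .05, .8, .05))
  p
})

glyph_class_names <- function(classes = c("digits", "letters", "all")) {
  classes <- match.arg(classes)
  switch(classes,
         digits = as.character(0:9),
         letters = LETTERS,
         all = c(as.character(0:9), LETTERS))
}

#' Variability parameters of the synthetic glyph generator
#'
#' Controls the intra-class variability emulating natural handwriting:
#' a random affine jitter (rotation, translation, isotropic scale), a
#' sampled stroke width, Gaussian blur, and additive pixel noise.  All
#' draws are uniform over the stated ranges (noise is Gaussian).
#'
#' @param rotation_range max absolute rotation, degrees.
#' @param translation_range max absolute translation, pixels, per axis.
#' @param scale_range max relative deviation of the isotropic scale factor
#'   (0.1 means scales in `[0.9, 1.1]`).
#' @param stroke_width_range length-2 vector, stroke width bounds in pixels.
#' @param noise_sd standard deviation of additive pixel noise (intensity
#'   units; images are clipped back to `[0, 1]`).
#' @param blur_sd Gaussian blur standard deviation in pixels (0 disables).
#' @return An object of class `"glyph_gen_params"`.
#' @export
glyph_gen_params <- function(rotation_range = 12, translation_range = 1.8,
                             scale_range = 0.12,
                             stroke_width_range = c(1.8, 3.2),
                             noise_sd = 0.05, blur_sd = 0.6) {
  if (rotation_range < 0 || translation_range < 0 || scale_range < 0 ||
      noise_sd < 0 || blur_sd < 0)
    stop_bad("all glyph variability ranges must be non-negative")
  if (length(stroke_width_range) != 2L || any(stroke_width_range <= 0) ||
      diff(stroke_width_range) < 0)
    stop_bad("'stroke_width_range' must be two positive non-decreasing values")
  structure(list(rotation_range = rotation_range,
                 translation_range = translation_range,
                 scale_range = scale_range,
                 stroke_width_range = stroke_width_range,
                 noise_sd = noise_sd, blur_sd = blur_sd),
            class = "glyph_gen_params")
}

# Pixel-centre grid of the 28x28 canvas, columns (x, y), 0-based pixel
# coordinates with y up (row 0 = top).
glyph_grid <- local({
  size <- 28L
  gx <- rep(0:(size - 1L), each = size)      # column index
  gy <- rep((size - 1L):0, times = size)     # y up within column
  cbind(x = gx, y = gy)
})

# Distance from each grid point (n x 2) to segment p-q.
dist_to_segment <- function(px, py, p, q) {
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  len2 <- vx * vx + vy * vy
  if (len2 < 1e-12) return(sqrt((px - p[1])^2 + (py - p[2])^2))
  t <- ((px - p[1]) * vx + (py - p[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - p[1] - t * vx)^2 + (py - p[2] - t * vy)^2)
}

gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  r <- max(1L, ceiling(2 * sd))
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  k <- k / sum(k)
  n <- nrow(img)
  pad <- function(m) m[pmin(pmax(seq_len(n + 2L * r) - r, 1L), n), , drop = FALSE]
  # separable: rows then columns
  m <- pad(img)
  rows <- vapply(seq_len(n), function(i) {
    colSums(m[i:(i + 2L * r), , drop = FALSE] * k)
  }, numeric(ncol(img)))
  m2 <- t(rows)
  m2 <- t(pad(t(m2)))
  out <- vapply(seq_len(n), function(j) {
    rowSums(m2[, j:(j + 2L * r), drop = FALSE] *
              matrix(k, nrow(m2), 2L * r + 1L, byrow = TRUE))
  }, numeric(nrow(img)))
  out
}

#' Render one synthetic glyph image
#'
#' Renders the class's stroke skeleton on the 28x28 canvas with a random
#' affine jitter, stroke width, blur, and pixel noise, drawn from the
#' current RNG state (seed with `set.seed()` for bit-identical images).
#' With all ranges and noise at zero the undistorted prototype is returned.
#'
#' @param class_id class identifier: a single character in
#'   `c(0:9, LETTERS)` or a 0-based index into [glyph_class_names()]'s
#'   `"all"` inventory.
#' @param params a [glyph_gen_params()].
#' @return 28x28 numeric matrix with values in `[0, 1]` (row 1 = top).
#' @examples
#' set.seed(1)
#' img <- generate_glyph("A")
#' dim(img)
#' @export
generate_glyph <- function(class_id, params = glyph_gen_params()) {
  all_names <- glyph_class_names("all")
  if (is.numeric(class_id)) {
    if (class_id < 0 || class_id >= length(all_names))
      stop_bad("numeric class_id %g out of range [0, %d)", class_id,
               length(all_names))
    class_id <- all_names[class_id + 1L]
  }
  class_id <- as.character(class_id)
  proto <- glyph_prototypes[[class_id]]
  if (is.null(proto)) stop_bad("unknown glyph class '%s'", class_id)

  # sample jitter
  theta <- stats::runif(1, -params$rotation_range, params$rotation_range) *
    pi / 180
  tx <- stats::runif(1, -params$translation_range, params$translation_range)
  ty <- stats::runif(1, -params$translation_range, params$translation_range)
  sc <- stats::runif(1, 1 - params$scale_range, 1 + params$scale_range)
  w <- stats::runif(1, params$stroke_width_range[1], params$stroke_width_range[2])

  # skeleton in pixel coordinates (y up), with a margin
  margin <- 3.0
  span <- 28 - 1 - 2 * margin
  centre <- (28 - 1) / 2
  # inverse-transform the sampling grid so strokes need no resampling
  px <- glyph_grid[, 1] - centre - tx
  py <- glyph_grid[, 2] - centre - ty
  ct <- cos(-theta); st <- sin(-theta)
  rx <- (ct * px - st * py) / sc + centre
  ry <- (st * px + ct * py) / sc + centre

  d <- rep(Inf, nrow(glyph_grid))
  for (stroke in proto) {
    pts <- cbind(margin + stroke[, 1] * span, margin + stroke[, 2] * span)
    for (i in seq_len(nrow(pts) - 1L)) {
      d <- pmin(d, dist_to_segment(rx, ry, pts[i, ], pts[i + 1L, ]))
    }
  }
  edge <- 0.7
  inten <- pmin(pmax((w / 2 + edge - d) / edge, 0), 1)
  img <- matrix(inten, 28, 28)  # column-major: rows top-to-bottom

  img <- gaussian_blur(img, params$blur_sd)
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(784, 0, params$noise_sd), 28, 28)
  pmin(pmax(img, 0), 1)
}
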