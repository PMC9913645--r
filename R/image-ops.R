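## Image geometry primitives and ROI preprocessing.
##
## Images are plain numeric matrices (rows x cols, single channel). After
## preprocessing every patch is 128 x 128 with intensities in [0, 1].

#' Min-max normalize an image to [0, 1]
#'
#' Per-image min-max normalization; the original intensity range is kept in
#' the `"source_range"` attribute. A constant image maps to all zeros.
#'
#' @param x Numeric matrix of intensities (any range, e.g. raw 8/16-bit).
#' @return Numeric matrix in \[0, 1\] with a `source_range` attribute.
#' @export
normalize01 <- function(x) {
  if (!is.matrix(x) || length(x) == 0L) stop("image must be a non-empty matrix")
  if (anyNA(x) || any(!is.finite(x))) stop("image contains NA/Inf")
  rng <- range(x)
  out <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  attr(out, "source_range") <- rng
  out
}

## 1-D resampling weight matrix (n_out x n_in): triangle (bilinear) filter,
## support widened to the scale factor when downscaling (antialiasing).
resample_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  support <- max(1, scale)
  centers <- (seq_len(n_out) - 0.5) * scale + 0.5
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    j0 <- max(1L, floor(centers[i] - support))
    j1 <- min(n_in, ceiling(centers[i] + support))
    j <- j0:j1
    w <- pmax(0, 1 - abs(j - centers[i]) / support)
    if (sum(w) == 0) w[which.min(abs(j - centers[i]))] <- 1
    W[i, j] <- w / sum(w)
  }
  W
}

#' Resize an image with antialiased bilinear interpolation
#'
#' Separable triangle-filter resampling; when downscaling, the filter support
#' is widened by the scale factor so high frequencies are averaged rather
#' than aliased. Resizing to the same size is an exact identity.
#'
#' @param x Numeric matrix.
#' @param height,width Output dimensions in pixels.
#' @return Numeric matrix of dimension `height x width`.
#' @export
resize_bilinear <- function(x, height, width = height) {
  stopifnot(is.matrix(x), height >= 1, width >= 1)
  if (nrow(x) == height && ncol(x) == width) return(x)
  Wr <- resample_weights(nrow(x), height)
  Wc <- resample_weights(ncol(x), width)
  Wr %*% x %*% t(Wc)
}

#' Rotate an image about its center
#'
#' Bilinear resampling on the fixed 128x128 (or input-sized) canvas with
#' edge-clamped sampling. Multiples of 90 degrees are exact permutations of
#' the pixel grid.
#'
#' @param x Numeric matrix.
#' @param angle Rotation angle in degrees (counter-clockwise in row/col space).
#' @return Rotated matrix, same dimensions as `x`.
#' @export
rotate_image <- function(x, angle) {
  stopifnot(is.matrix(x))
  if (angle %% 360 == 0) return(x)
  h <- nrow(x); w <- ncol(x)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- rep(seq_len(h), times = w); cc <- rep(seq_len(w), each = h)
  ## inverse map: sample source coordinates rotated by -angle
  sr <- cy + cos(th) * (r - cy) + sin(th) * (cc - cx)
  sc <- cx - sin(th) * (r - cy) + cos(th) * (cc - cx)
  sr <- pmin(pmax(sr, 1), h); sc <- pmin(pmax(sc, 1), w)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  v <- x[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    x[cbind(r1, c0)] * fr * (1 - fc) +
    x[cbind(r0, c1)] * (1 - fr) * fc +
    x[cbind(r1, c1)] * fr * fc
  matrix(v, h, w)
}

#' Crop a tumor-centered region of interest
#'
#' Extracts a window centered on the tumor whose side is
#' `max(target, tumor_extent)`: the window grows beyond `target` pixels only
#' when the lesion itself is larger, so tumor boundaries are preserved.
#' Windows reaching past the image edge are padded by edge replication.
#' Windows larger than `target` are resized (antialiased bilinear) down to
#' `target x target`. The result is min-max normalized to \[0, 1\].
#'
#' @param image Numeric matrix (a CT slice, any size).
#' @param center Length-2 integer vector `(row, col)` of the tumor center.
#' @param extent Tumor bounding-box side in pixels.
#' @param target Output side length (default 128).
#' @return `target x target` matrix in \[0, 1\].
#' @export
crop_roi <- function(image, center, extent, target = 128L) {
  if (!is.matrix(image) || length(image) == 0L) stop("empty or non-matrix image")
  if (length(center) != 2L) stop("center must be (row, col)")
  r <- center[1]; cc <- center[2]
  if (r < 1 || r > nrow(image) || cc < 1 || cc > ncol(image))
    stop("tumor center outside image bounds")
  if (!is.finite(extent) || extent <= 0) stop("extent must be positive")
  side <- max(target, round(extent))
  start_r <- r - ceiling(side / 2) + 1
  start_c <- cc - ceiling(side / 2) + 1
  rows <- pmin(pmax(start_r:(start_r + side - 1), 1L), nrow(image))
  cols <- pmin(pmax(start_c:(start_c + side - 1), 1L), ncol(image))
  win <- image[rows, cols, drop = FALSE]
  if (side > target) win <- resize_bilinear(win, target, target)
  normalize01(win)
}

#' Augmentation settings
#'
#' Spatial (horizontal flip, rotation, crop-and-resize) and appearance
#' (brightness/contrast jitter) transformations. All probabilities 0 gives a
#' bit-exact identity.
#'
#' @param flip_p Probability of a horizontal flip.
#' @param rotate_p,max_rotate Probability and maximal magnitude (degrees) of
#'   a random rotation drawn uniformly from `[-max_rotate, max_rotate]`.
#' @param crop_p,crop_scale Probability of a random crop; the crop side is a
#'   uniform fraction in `crop_scale` of the image, then resized back.
#' @param jitter_p,brightness,contrast Probability of appearance jitter;
#'   brightness shift and contrast factor are drawn from `[-b, b]` and
#'   `[1 - c, 1 + c]`.
#' @return List of class `"augment_config"`.
#' @export
augment_config <- function(flip_p = 0.5, rotate_p = 0.5, max_rotate = 15,
                           crop_p = 0.5, crop_scale = c(0.8, 1.0),
                           jitter_p = 0.5, brightness = 0.2, contrast = 0.2) {
  structure(list(flip_p = flip_p, rotate_p = rotate_p, max_rotate = max_rotate,
                 crop_p = crop_p, crop_scale = crop_scale, jitter_p = jitter_p,
                 brightness = brightness, contrast = contrast),
            class = "augment_config")
}

#' Randomly augment a lesion patch
#'
#' Applies horizontal flip, rotation, crop-and-resize and brightness/contrast
#' jitter, each with its configured probability, using the current RNG stream
#' (call `set.seed()` beforehand for reproducibility). Labels and patient
#' identity are attached to the manifest, not the pixels, so they are
#' untouched by construction. Output is the same size as the input, in [0, 1].
#'
#' @param x Numeric matrix in \[0, 1\].
#' @param config An [augment_config()].
#' @return Augmented matrix.
#' @export
augment <- function(x, config = augment_config()) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (config$flip_p > 0 && stats::runif(1) < config$flip_p)
    x <- x[, ncol(x):1, drop = FALSE]
  if (config$rotate_p > 0 && stats::runif(1) < config$rotate_p)
    x <- rotate_image(x, stats::runif(1, -config$max_rotate, config$max_rotate))
  if (config$crop_p > 0 && stats::runif(1) < config$crop_p) {
    s <- stats::runif(1, config$crop_scale[1], config$crop_scale[2])
    side <- max(8L, round(n * s))
    if (side < n) {
      r0 <- sample.int(n - side + 1L, 1L)
      c0 <- sample.int(ncol(x) - side + 1L, 1L)
      x <- resize_bilinear(x[r0:(r0 + side - 1L), c0:(c0 + side - 1L)], n, ncol(x))
    }
  }
  if (config$jitter_p > 0 && stats::runif(1) < config$jitter_p) {
    b <- stats::runif(1, -config$brightness, config$brightness)
    cf <- 1 + stats::runif(1, -config$contrast, config$contrast)
    x <- (x - 0.5) * cf + 0.5 + b
  }
  pmin(pmax(x, 0), 1)
}
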