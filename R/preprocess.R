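#' Preprocessing configuration
#'
#' Parameters for the single denoise-and-normalize pass every frame receives
#' before clustering.
#'
#' @param gaussian_sigma Standard deviation (pixels) of the Gaussian
#'   smoothing kernel; `0` disables smoothing. Default 1.0.
#' @param median_radius Radius of the square median window (side
#'   `2*radius + 1`); `0` disables the median filter. Default 1.
#' @param polarity `"vessels_bright"` if contrast-filled vessels are brighter
#'   than background (the package's working convention), `"vessels_dark"` for
#'   conventional DSA display exports, in which case normalized intensities
#'   are inverted so that high cluster indices always mean high vessel
#'   signal.
#' @param clip_percentiles Length-2 numeric, low/high percentile levels used
#'   as the 0 and 1 anchors of normalization. Default `c(0.5, 99.5)`.
#' @param downsample_factor Integer block size for optional block-mean
#'   downsampling; default 1 (the quantitative path never downsamples).
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(gaussian_sigma = 1.0, median_radius = 1L,
                              polarity = c("vessels_bright", "vessels_dark"),
                              clip_percentiles = c(0.5, 99.5),
                              downsample_factor = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(gaussian_sigma >= 0, median_radius >= 0,
            length(clip_percentiles) == 2,
            clip_percentiles[1] < clip_percentiles[2],
            clip_percentiles[1] >= 0, clip_percentiles[2] <= 100,
            downsample_factor >= 1)
  structure(list(gaussian_sigma = gaussian_sigma,
                 median_radius = as.integer(median_radius),
                 polarity = polarity,
                 clip_percentiles = clip_percentiles,
                 downsample_factor = as.integer(downsample_factor)),
            class = "preprocess_config")
}

#' Denoise a raw frame
#'
#' Gaussian smoothing (symmetric/reflect boundary, kernel truncated at
#' `ceiling(3*sigma)`) applied first, then a median filter over a square
#' window of side `2*median_radius + 1`. Values are rounded half-up back to
#' integers after the Gaussian, so the output remains an 8-bit raster.
#'
#' @param image Integer gray-level matrix.
#' @param cfg A [preprocess_config()].
#' @return Integer matrix, same shape, values in \[0, 255\].
#' @export
denoise <- function(image, cfg = preprocess_config()) {
  validate_raw_image(image)
  x <- image
  if (cfg$gaussian_sigma > 0) {
    x <- round_half_up(gaussian_filter_cpp(x + 0, cfg$gaussian_sigma))
  }
  if (cfg$median_radius > 0) {
    x <- median_filter_cpp(x + 0, cfg$median_radius)
  }
  out <- matrix(as.integer(x), nrow = nrow(image), ncol = ncol(image))
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Normalize a frame to the unit interval
#'
#' Values are clipped to the low/high percentile levels of the frame's own
#' intensity distribution and affinely mapped so clip-low maps to 0 and
#' clip-high to 1; under `vessels_dark` polarity the result is then inverted
#' (`x -> 1 - x`). The applied parameters are recorded in the `"provenance"`
#' attribute.
#'
#' @param image Integer gray-level matrix.
#' @param cfg A [preprocess_config()].
#' @return Numeric matrix in \[0, 1\] with a `"provenance"` attribute.
#' @export
normalize_image <- function(image, cfg = preprocess_config()) {
  validate_raw_image(image)
  q <- stats::quantile(image, probs = cfg$clip_percentiles / 100,
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    stop("degenerate intensity range: clip levels coincide (",
         q[1], ")", call. = FALSE)
  }
  x <- pmin(pmax(image, q[1]), q[2])
  x <- (x - q[1]) / (q[2] - q[1])
  if (cfg$polarity == "vessels_dark") x <- 1 - x
  out <- matrix(x, nrow = nrow(image), ncol = ncol(image))
  attr(out, "provenance") <- list(
    clip_levels = q, clip_percentiles = cfg$clip_percentiles,
    polarity = cfg$polarity, gaussian_sigma = cfg$gaussian_sigma,
    median_radius = cfg$median_radius, filter_order = "gaussian_then_median",
    rounding = "half_up")
  out
}

#' Block-mean downsample
#'
#' Averages `factor x factor` pixel blocks and rounds half-up. Both image
#' dimensions must be divisible by `factor` (no padding is ever applied).
#' Downsampling is intended for figure preparation only and is excluded from
#' the quantitative path by default.
#'
#' @param image Integer gray-level matrix.
#' @param factor Positive integer block size.
#' @return Integer matrix of shape `dim(image) / factor`.
#' @export
downsample <- function(image, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(image)
  if (nrow(image) %% factor != 0L || ncol(image) %% factor != 0L) {
    stop("image dimensions ", nrow(image), "x", ncol(image),
         " not divisible by factor ", factor, call. = FALSE)
  }
  nr <- nrow(image) %/% factor
  nc <- ncol(image) %/% factor
  ri <- rep(seq_len(nr), each = factor)
  ci <- rep(seq_len(nc), each = factor)
  sums <- rowsum(t(rowsum(image + 0, ri)), ci)  # block sums, transposed
  out <- round_half_up(t(sums) / factor^2)
  matrix(as.integer(out), nrow = nr, ncol = nc)
}
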