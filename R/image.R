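#' Construct an 8-bit RGB image
#'
#' Wraps an H x W x 3 numeric array of intensities in \[0, 255\] (stored as
#' doubles; values need not be integral until written to disk).
#'
#' @param pixels H x W x 3 numeric array with values in \[0, 255\].
#' @return An object of class `rgb_image` (the array with a class attribute).
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("empty image", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, range [%.1f, %.1f]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

as_pixel_array <- function(img) {
  if (inherits(img, "rgb_image")) unclass(img) else img
}

#' Convert an RGB image to luminance
#'
#' Uses the ITU-R BT.601 luma weights 0.299 R + 0.587 G + 0.114 B.  The
#' result is kept real-valued (not quantized) so downstream statistics such
#' as the mean luminance are exact.
#'
#' @param img An `rgb_image` or H x W x 3 array in \[0, 255\].
#' @return H x W numeric matrix of luminance values in \[0, 255\].
#' @export
rgb_to_gray <- function(img) {
  px <- as_pixel_array(img)
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  if (prod(dim(px)[1:2]) == 0L) stop("empty image", call. = FALSE)
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  if (is.null(dim(g))) g <- matrix(g, dim(px)[1], dim(px)[2])
  g
}

#' Mean luminance of a grayscale image
#'
#' @param gray Numeric matrix of luminance values.
#' @return Scalar arithmetic mean over all pixels.
#' @export
mean_luminance <- function(gray) {
  if (length(gray) == 0L) stop("empty grayscale image", call. = FALSE)
  mean(gray)
}

#' Classify the illumination regime of an image
#'
#' Routes by mean luminance mu: `low_light` when mu < t_low, `overexposed`
#' when mu >= t_high, `normal_light` otherwise.  The overexposure test is
#' applied before the default, so mu exactly at `t_high` is overexposed and
#' mu exactly at `t_low` is normal.
#'
#' @param mu Mean luminance in \[0, 255\].
#' @param t_low,t_high Regime thresholds (defaults 60 and 150).
#' @return A list of class `illumination_label` with elements `label`
#'   (one of `"low_light"`, `"normal_light"`, `"overexposed"`) and
#'   `mean_luminance`.
#' @export
classify_illumination <- function(mu, t_low = 60, t_high = 150) {
  if (t_low >= t_high)
    stop("`t_low` must be strictly less than `t_high`", call. = FALSE)
  if (mu < 0 || mu > 255) stop("`mu` must lie in [0, 255]", call. = FALSE)
  label <- if (mu < t_low) "low_light"
           else if (mu >= t_high) "overexposed"
           else "normal_light"
  structure(list(label = label, mean_luminance = mu),
            class = "illumination_label")
}

#' @export
print.illumination_label <- function(x, ...) {
  cat(sprintf("<illumination: %s (mean luminance %.2f)>\n",
              x$label, x$mean_luminance))
  invisible(x)
}

# clip + quantize a working array back to an 8-bit image
finalize_rgb <- function(px) {
  rgb_image(array(pmin(255, pmax(0, round(px))), dim = dim(px)))
}
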