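#' Generate median-binarized correlated binary textures
#'
#' A synthetic stand-in for binarized grayscale natural images: isotropic
#' Gaussian random fields smoothed at a controllable correlation length and
#' binarized at each image's own median pixel intensity. With
#' `correlation_length = 0` the images are iid fair bits; larger values give
#' spatially correlated blobs, so the dependence of downstream encoding
#' statistics on input correlations can be probed.
#'
#' @param n_images Number of images.
#' @param height,width Image dimensions in pixels.
#' @param correlation_length Standard deviation (pixels) of the isotropic
#'   Gaussian smoothing kernel; 0 disables smoothing.
#' @param seed Integer seed.
#' @return A `binary_images` object: list with `images` (an `n_images` x
#'   `height*width` 0/1 matrix, pixels in row-major raster order), `height`,
#'   `width`, `correlation_length`, `threshold_rule = "median"`.
#' @examples
#' imgs <- generate_binary_textures(3, 16, 16, correlation_length = 2, seed = 1)
#' rowMeans(imgs$images)
#' @export
generate_binary_textures <- function(n_images, height, width,
                                     correlation_length = 0, seed = 1L) {
  check_count(n_images, "n_images")
  check_count(height, "height")
  check_count(width, "width")
  if (!is.finite(correlation_length) || correlation_length < 0) {
    abort("`correlation_length` must be >= 0.")
  }
  withr::local_seed(as.integer(seed))
  npix <- height * width
  out <- matrix(0L, nrow = n_images, ncol = npix)
  for (k in seq_len(n_images)) {
    z <- matrix(stats::rnorm(npix), nrow = height, ncol = width)
    if (correlation_length > 0) {
      z <- gaussian_smooth_2d(z, correlation_length)
    }
    # row-major raster order: rows top-to-bottom, left-to-right within a row
    out[k, ] <- as.integer(t(z > stats::median(z)))
  }
  structure(
    list(images = out, height = as.integer(height), width = as.integer(width),
         correlation_length = correlation_length, threshold_rule = "median",
         seed = as.integer(seed)),
    class = "binary_images"
  )
}

#' @export
print.binary_images <- function(x, ...) {
  cat(sprintf(
    "<binary_images> %d %dx%d median-binarized textures (correlation length %.3g px)\n",
    nrow(x$images), x$height, x$width, x$correlation_length))
  invisible(x)
}

# circular (periodic) 2D convolution with an isotropic Gaussian kernel via FFT
gaussian_smooth_2d <- function(z, sd) {
  h <- nrow(z); w <- ncol(z)
  dy <- pmin(0:(h - 1), h - 0:(h - 1))
  dx <- pmin(0:(w - 1), w - 0:(w - 1))
  kern <- exp(-outer(dy^2, dx^2, "+") / (2 * sd^2))
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / (h * w)
}
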