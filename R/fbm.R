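#' Grayscale image container
#'
#' Light-weight container for a 2D intensity field together with its pixel
#' size and bit depth.  Most functions in the package also accept a plain
#' numeric matrix, which is promoted with the defaults below.
#'
#' @param values numeric matrix of intensities (finite; both dims >= 32).
#' @param pixel_size pixel size in micrometres (default 50, the resolution of
#'   standard digital screening mammograms).
#' @param bit_depth `8`, `12` or `"float"`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(values, pixel_size = 50, bit_depth = "float") {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop_bad_arg("image values must be finite")
  if (min(dim(values)) < 32L) stop_bad_arg("image must be at least 32 pixels on each side")
  if (!(identical(bit_depth, "float") || bit_depth %in% c(8, 12)))
    stop_bad_arg("bit_depth must be 8, 12 or \"float\"")
  structure(list(values = values, pixel_size = pixel_size, bit_depth = bit_depth),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %s-bit, %g um/px>\n",
              nrow(x$values), ncol(x$values),
              if (identical(x$bit_depth, "float")) "float" else x$bit_depth,
              x$pixel_size))
  invisible(x)
}

as_gray_image <- function(x, ...) {
  if (inherits(x, "gray_image")) x else gray_image(x, ...)
}

## raw periodic synthesis of a power-law Gaussian field at size n
fbm_periodic <- function(n, hurst, seed) {
  with_seed(seed, {
    k <- fft_freq(n)
    kx <- matrix(k, n, n, byrow = TRUE)
    ky <- matrix(k, n, n)
    kk <- sqrt(kx * kx + ky * ky)
    kk[1, 1] <- Inf                                  # zero the DC mode
    amp <- kk^(-(hurst + 1))                         # power |k|^-(2H+2)
    w <- matrix(stats::rnorm(n * n), n, n)
    Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (n * n)
  })
}

#' Generate a fractional Brownian surface with known Hurst exponent
#'
#' Synthesizes an isotropic Gaussian random surface whose spectral density
#' follows \eqn{|k|^{-(2H+2)}} by Fourier spectral filtering of
#' Hermitian-symmetric white noise.  The surface is synthesized at
#' `oversample` times the requested side and center-cropped, so that the
#' returned patch carries low-frequency content beyond its own extent and
#' periodic wrap-around artifacts are avoided.
#'
#' @param side patch side in pixels (>= 32; powers of two are fastest).
#' @param hurst target Hurst exponent, strictly inside (0, 1).
#' @param seed integer seed; identical seeds give bit-identical surfaces.
#' @param bit_depth `"float"` (default) returns the raw surface; `8` or `12`
#'   rescales to the full integer range of that depth and rounds.
#' @param oversample synthesis size multiplier before cropping (default 2).
#' @return A [gray_image].
#' @examples
#' img <- generate_fbm_surface(64, hurst = 0.5, seed = 1)
#' @export
generate_fbm_surface <- function(side, hurst, seed, bit_depth = "float",
                                 oversample = 2L) {
  if (!is_count(side) || side < 32) stop_bad_arg("side must be an integer >= 32")
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop_bad_arg("hurst must lie strictly inside (0, 1)")
  n <- as.integer(round(side * oversample))
  f <- fbm_periodic(n, hurst, seed)
  i0 <- (n - side) %/% 2L
  f <- f[(i0 + 1L):(i0 + side), (i0 + 1L):(i0 + side)]
  if (!identical(bit_depth, "float")) {
    top <- 2^bit_depth - 1
    rng <- range(f)
    f <- round((f - rng[1]) / (rng[2] - rng[1]) * top)
  }
  gray_image(f, bit_depth = bit_depth)
}
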