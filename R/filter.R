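#' Low-pass filter a binary plane and re-quantize to one bit
#'
#' Smooths a {0,1} plane with a unit-DC kernel and thresholds the result back
#' to one bit. With the default 7x7 Hanning kernel and threshold 0.5 this acts
#' as a weighted majority vote over each pixel's neighborhood: isolated
#' spurious pixels (in either polarity) are removed while solid regions are
#' preserved. Ties at the threshold map to 1.
#'
#' Borders are handled by reflect (mirror) padding, which avoids the spurious
#' zeros that zero padding would introduce along the edges of all-bright skin.
#'
#' @param plane Integer 0/1 matrix.
#' @param kernel Nonnegative convolution kernel with unit sum
#'   (default [make_hanning_kernel()] of size 7).
#' @param threshold Quantization threshold in (0, 1); output is 1 where the
#'   filtered value is `>= threshold`.
#' @return Integer 0/1 matrix, same shape as `plane`.
#' @export
lowpass_quantize <- function(plane, kernel = make_hanning_kernel(7L),
                             threshold = 0.5) {
  assert_binary_matrix(plane, "plane")
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  f <- convolve2_reflect(plane, kernel)
  q <- plane
  q[] <- as.integer(f >= threshold)
  q
}

#' 2D convolution with reflect (mirror) padding
#'
#' Correlates `x` with `kernel` under edge-inclusive symmetric padding
#' (`... x3 x2 x1 | x1 x2 ... xn | xn xn-1 ...`). For the symmetric kernels
#' used in this package, correlation and convolution coincide.
#'
#' @param x Numeric matrix.
#' @param kernel Odd-sized square numeric matrix.
#' @return Numeric matrix, same shape as `x`.
#' @export
convolve2_reflect <- function(x, kernel) {
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel) ||
      nrow(kernel) %% 2L == 0L) {
    stop("`kernel` must be an odd-sized square matrix", call. = FALSE)
  }
  k <- nrow(kernel)
  pad <- (k - 1L) %/% 2L
  h <- nrow(x)
  w <- ncol(x)
  if (h <= pad || w <= pad) {
    stop("input smaller than kernel half-width", call. = FALSE)
  }
  ri <- c(pad:1, 1:h, h:(h - pad + 1L))
  ci <- c(pad:1, 1:w, w:(w - pad + 1L))
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (kernel[i, j] == 0) next
      out <- out + kernel[i, j] * xp[i:(i + h - 1L), j:(j + w - 1L)]
    }
  }
  out
}
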