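#' 2D Hanning (Hann) low-pass kernel
#'
#' Builds the separable 2D raised-cosine window used to smooth each binary
#' MSB plane before re-quantization: the outer product of the 1D Hann window
#' `w[n] = 0.5 * (1 - cos(2 * pi * n / (size - 1)))`, `n = 0..size-1`,
#' normalized to unit sum so the filter has unit DC gain. The 1D window is
#' zero at both endpoints, so a `size = 7` kernel has an effective support of
#' 5 x 5 inside its 7 x 7 frame; its center weight is exactly 1/9.
#'
#' @param size Odd kernel side length, at least 3 (default 7).
#' @return A `size x size` numeric matrix of nonnegative weights summing to 1.
#' @examples
#' k <- make_hanning_kernel(7)
#' sum(k)           # 1
#' k[4, 4]          # 1/9
#' @export
make_hanning_kernel <- function(size = 7L) {
  if (length(size) != 1L || is.na(size) || size != floor(size) ||
      size < 3L || size %% 2L == 0L) {
    stop("`size` must be an odd integer >= 3", call. = FALSE)
  }
  w <- hann_window(size)
  k <- outer(w, w)
  k / sum(k)
}

#' 1D Hann window
#'
#' Unnormalized raised-cosine taper with zero endpoints; for `size = 7` it is
#' `c(0, 0.25, 0.75, 1, 0.75, 0.25, 0)`.
#'
#' @param size Window length.
#' @return Numeric vector of length `size`.
#' @export
hann_window <- function(size) {
  n <- seq_len(size) - 1L
  0.5 * (1 - cos(2 * pi * n / (size - 1L)))
}
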