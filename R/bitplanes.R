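#' Extract one bit plane of one color channel
#'
#' Each 8-bit channel value decomposes as `sum_i plane_i * 2^i`; this returns
#' the binary image formed by bit `bit` of every pixel of the requested
#' channel. Bit 7 is the most significant bit (value >= 128).
#'
#' @param image An [rgb_image()].
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param bit Bit index in 0--7 (7 = most significant).
#' @return Integer 0/1 matrix, same shape as the image.
#' @export
decompose_bit_plane <- function(image, channel = c("R", "G", "B"), bit) {
  channel <- match.arg(channel)
  if (length(bit) != 1L || is.na(bit) || bit != floor(bit) || bit < 0 || bit > 7) {
    stop("`bit` must be an integer in [0, 7]", call. = FALSE)
  }
  v <- img_channel(image, channel)
  p <- v
  p[] <- as.integer(bitwAnd(as.integer(v), bitwShiftL(1L, as.integer(bit))) != 0L)
  p
}

#' Extract the three MSB planes of an RGB image
#'
#' Retains only the most significant bit plane of each of the R, G and B
#' channels: for `bit = 7` the plane is 1 exactly where the channel value is
#' at least 128. Other bit indices are accepted as a configuration hook for
#' exploring the less significant planes, but only bit 7 is part of the
#' validated segmentation pipeline.
#'
#' @inheritParams decompose_bit_plane
#' @return Named list of three 0/1 integer matrices: `r`, `g`, `b`.
#' @export
extract_msb_planes <- function(image, bit = 7L) {
  list(
    r = decompose_bit_plane(image, "R", bit),
    g = decompose_bit_plane(image, "G", bit),
    b = decompose_bit_plane(image, "B", bit)
  )
}
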