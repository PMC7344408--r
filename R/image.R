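#' 8-bit RGB raster image
#'
#' The pipeline's input container: a `height x width x 3` integer array with
#' values in 0--255, channels ordered R, G, B. Coordinates are 1-based
#' `(row, col)` with row 1 at the top, matching R's matrix indexing.
#'
#' @param x A numeric array of dimension `c(h, w, 3)`, a matrix (replicated to
#'   three identical channels), or an existing `rgb_image`.
#' @return An `rgb_image` object.
#' @examples
#' img <- rgb_image(array(c(200, 160, 140), dim = c(1, 1, 3)))
#' img_channel(img, "G")
#' @export
rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) return(x)
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L) {
    stop("`x` must be an h x w x 3 array or a matrix", call. = FALSE)
  }
  v <- as.vector(x)
  if (anyNA(v) || any(v < 0) || any(v > 255) || any(v != floor(v))) {
    stop("rgb_image values must be integers in [0, 255]", call. = FALSE)
  }
  out <- array(as.integer(x), dim = dim(x))
  class(out) <- "rgb_image"
  out
}

#' Extract one color channel as an integer matrix
#'
#' @param image An [rgb_image()].
#' @param channel `"R"`, `"G"` or `"B"`.
#' @return Integer matrix of channel intensities (0--255).
#' @export
img_channel <- function(image, channel = c("R", "G", "B")) {
  channel <- match.arg(channel)
  image <- rgb_image(image)
  ci <- match(channel, c("R", "G", "B"))
  m <- unclass(image)[, , ci, drop = TRUE]
  if (!is.matrix(m)) m <- matrix(m, nrow = dim(image)[1L])
  m
}

#' @export
dim.rgb_image <- function(x) dim(unclass(x))

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 channels (8-bit)\n", d[1L], d[2L]))
  invisible(x)
}

# internal: validate a {0,1} integer matrix (bit plane / mask)
assert_binary_matrix <- function(m, what = "plane") {
  if (!is.matrix(m)) stop(sprintf("%s must be a matrix", what), call. = FALSE)
  if (!all(m == 0L | m == 1L)) {
    stop(sprintf("%s must contain only 0 and 1", what), call. = FALSE)
  }
  invisible(m)
}

# internal: shape equality
assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("%s must share the same height and width", what), call. = FALSE)
  }
  invisible(NULL)
}
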