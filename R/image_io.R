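#' Read a dermoscopic image as an 8-bit RGB raster
#'
#' Decodes PNG, JPEG or TIFF files. Grayscale inputs are replicated to three
#' identical channels; an alpha channel is dropped. Images stored with more
#' than 8 bits per sample are rejected rather than silently rescaled, because
#' the bit-plane stages of the pipeline are defined on 8-bit values.
#'
#' @param path Path to a PNG (`.png`), JPEG (`.jpg`/`.jpeg`) or TIFF
#'   (`.tif`/`.tiff`) file.
#' @return An [rgb_image()].
#' @export
load_rgb_image <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 2L) {
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  } else if (dim(arr)[3L] == 1L) {
    arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  } else if (dim(arr)[3L] >= 4L) {
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (dim(arr)[3L] == 2L) { # gray + alpha
    arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  }
  rgb_image(array(as.integer(round(arr * 255)), dim = dim(arr)))
}

# internal: decode by extension, values scaled to [0,1]; rejects >8-bit depth
read_raster <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      hdr <- readBin(path, "raw", n = 26L)
      if (length(hdr) >= 25L && as.integer(hdr[25L]) > 8L) {
        stop(sprintf("unsupported format: '%s' has %d-bit samples (only 8-bit supported)",
                     path, as.integer(hdr[25L])), call. = FALSE)
      }
      png::readPNG(path)
    },
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, info = TRUE)
      bps <- attr(x, "bits.per.sample")
      if (!is.null(bps) && any(bps > 8L)) {
        stop(sprintf("unsupported format: '%s' has %d-bit samples (only 8-bit supported)",
                     path, max(bps)), call. = FALSE)
      }
      x
    },
    stop(sprintf("cannot read image '%s': unsupported extension '%s'", path, ext),
         call. = FALSE)
  )
  arr
}

#' Read a binary ground-truth lesion mask
#'
#' Any nonzero pixel (maximum over channels for multi-channel files) maps to 1,
#' zero maps to 0, so both 0/1 and 0/255 mask conventions are accepted.
#'
#' @inheritParams load_rgb_image
#' @return An integer matrix of 0/1, 1 = lesion.
#' @export
load_mask <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1L, 2L), max)
  m <- matrix(as.integer(arr > 0), nrow = nrow(arr))
  m
}

#' Write an 8-bit RGB image losslessly
#'
#' All artifact outputs are written as PNG: the bit-plane logic is sensitive to
#' lossy compression, so lossy formats are accepted on read only.
#'
#' @param image An [rgb_image()].
#' @param path Output path; written as PNG regardless of extension.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  image <- rgb_image(image)
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Write a binary mask as a black/white PNG
#'
#' @param mask Integer 0/1 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_binary_matrix(mask, "mask")
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' Write a 4-level segmentation map as a grayscale PNG
#'
#' Levels 0--3 are mapped to intensities 0, 85, 170, 255 so the map is
#' directly viewable.
#'
#' @param levels Integer matrix with values in 0--3 (see [sum_planes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_level_map <- function(levels, path) {
  if (!all(levels %in% 0:3)) stop("level map values must be in 0..3", call. = FALSE)
  png::writePNG(levels * 85 / 255, target = path)
  invisible(path)
}

#' Paint a lesion contour onto a copy of the image
#'
#' Writes a lossless PNG copy of `image` with every contour pixel painted a
#' fixed highlight color; the input image is not modified. Repeated contour
#' vertices paint the same pixel once.
#'
#' @param image An [rgb_image()].
#' @param contour A tibble with `row`/`col` columns as returned by
#'   [trace_border()]; may have zero rows.
#' @param path Output path.
#' @param color Highlight color, integer RGB triple (default pure red).
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, contour, path, color = c(255L, 0L, 0L)) {
  image <- rgb_image(image)
  arr <- unclass(image)
  h <- dim(arr)[1L]
  w <- dim(arr)[2L]
  if (nrow(contour) > 0L) {
    if (any(contour$row < 1L | contour$row > h | contour$col < 1L | contour$col > w)) {
      stop("contour coordinates lie outside image bounds", call. = FALSE)
    }
    for (ci in 1:3) {
      arr[cbind(contour$row, contour$col, ci)] <- color[ci]
    }
  }
  png::writePNG(arr / 255, target = path)
  invisible(path)
}
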