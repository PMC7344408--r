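#' Segment a dermoscopic image and trace the lesion border
#'
#' Runs the full pipeline: extract the most-significant-bit plane of each RGB
#' channel, smooth each plane with a shared 7x7 Hanning kernel and re-quantize
#' to one bit, sum the three planes into a 4-level map, select the lesion mask
#' from the levels, and trace its border. No image enhancement, resizing,
#' color-space conversion or hair removal is performed: the bit-plane logic
#' plus the majority-vote filter is the whole method, and the pipeline is
#' fully deterministic.
#'
#' @param image An [rgb_image()] (or path-free in-memory raster from
#'   [load_rgb_image()] / [generate_fixture()]).
#' @param config A [segmentation_config()].
#' @return A `lesion_segmentation` object: list with elements `levels`
#'   (0--3 integer matrix), `mask` (0/1 integer matrix), `contour` (tibble of
#'   `row`/`col`) and `config`.
#' @examples
#' fx <- generate_fixture(synthetic_spec(size = 96L, radius = 25, seed = 1L))
#' seg <- segment_lesion(fx$image)
#' glance(seg)
#' @export
segment_lesion <- function(image, config = segmentation_config()) {
  image <- rgb_image(image)
  planes <- extract_msb_planes(image, config$bit_index)
  kernel <- make_hanning_kernel(7L)
  q <- lapply(planes, lowpass_quantize, kernel = kernel,
              threshold = config$quantize_threshold)
  levels <- sum_planes(q$r, q$g, q$b)
  mask <- lesion_mask_from_levels(levels, config)
  contour <- trace_border(mask)
  structure(
    list(levels = levels, mask = mask, contour = contour, config = config),
    class = "lesion_segmentation"
  )
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<lesion_segmentation> %d x %d px; lesion area %d px (%.1f%%); contour length %d\n",
    d[1L], d[2L], sum(x$mask), 100 * mean(x$mask), nrow(x$contour)
  ))
  invisible(x)
}

#' @rdname segment_lesion
#' @param x A `lesion_segmentation` object.
#' @param ... Unused.
#' @return `tidy()`: the ordered border contour as a tibble with `point`
#'   (step index), `row`, `col`.
#' @exportS3Method
tidy.lesion_segmentation <- function(x, ...) {
  tibble::tibble(
    point = seq_len(nrow(x$contour)),
    row = x$contour$row,
    col = x$contour$col
  )
}

#' @rdname segment_lesion
#' @return `glance()`: a one-row tibble with the mask area (pixels and
#'   fraction), contour length, and the pixel count of each of the four
#'   levels.
#' @exportS3Method
glance.lesion_segmentation <- function(x, ...) {
  lev <- tabulate(x$levels + 1L, nbins = 4L)
  tibble::tibble(
    height = nrow(x$mask),
    width = ncol(x$mask),
    mask_area = sum(x$mask),
    mask_fraction = mean(x$mask),
    contour_length = nrow(x$contour),
    n_level0 = lev[1L],
    n_level1 = lev[2L],
    n_level2 = lev[3L],
    n_level3 = lev[4L]
  )
}
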