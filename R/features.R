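#' Color histograms of each segmented region
#'
#' Tallies, for every region and every RGB channel, how many pixels of that
#' region carry each 8-bit intensity. Regions default to the four levels of
#' the segmentation map; any integer labelling (e.g. a 0/1 lesion mask, or
#' connected-component labels) can be supplied instead. Histograms are raw
#' counts, not densities — counts are lossless and normalization is left to
#' the presentation layer. Regions absent from the image yield all-zero
#' histograms.
#'
#' For every `(region, channel)` pair the bin counts sum to the region's pixel
#' count, and the region pixel counts sum to the image pixel count.
#'
#' @param image An [rgb_image()].
#' @param regions Integer matrix of region labels, same shape as the image
#'   (typically the [sum_planes()] level map).
#' @param region_ids Region labels to tabulate (default `0:3`, the level
#'   classes; pass `0:1` for a lesion mask).
#' @return A tibble with columns `region` (integer label), `channel`
#'   (`"R"`/`"G"`/`"B"`), `intensity` (0--255) and `count`; 256 rows per
#'   region/channel pair.
#' @examples
#' fx <- generate_fixture(synthetic_spec(size = 64L, radius = 18, seed = 2L))
#' seg <- segment_lesion(fx$image)
#' h <- region_color_histograms(fx$image, seg$levels)
#' dplyr::count(h, region, wt = count) # 3x the pixel count per region
#' @export
region_color_histograms <- function(image, regions, region_ids = 0:3) {
  image <- rgb_image(image)
  if (!is.matrix(regions)) stop("`regions` must be a matrix", call. = FALSE)
  assert_same_shape(unclass(image), regions, "image and regions")
  chans <- list(R = img_channel(image, "R"),
                G = img_channel(image, "G"),
                B = img_channel(image, "B"))
  rows <- purrr::map(sort(unique(as.integer(region_ids))), function(rg) {
    in_region <- regions == rg
    purrr::imap(chans, function(v, nm) {
      counts <- tabulate(v[in_region] + 1L, nbins = 256L)
      tibble::tibble(region = rg, channel = nm,
                     intensity = 0:255, count = as.integer(counts))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Pixel count of each region of a label map
#'
#' @param regions Integer label matrix.
#' @param region_ids Labels to report (default `0:3`).
#' @return A tibble with columns `region` and `n_pixels`.
#' @export
region_pixel_counts <- function(regions, region_ids = 0:3) {
  ids <- sort(unique(as.integer(region_ids)))
  tibble::tibble(
    region = ids,
    n_pixels = vapply(ids, function(rg) sum(regions == rg), integer(1))
  )
}

#' Serialize region histograms to JSON
#'
#' Written as region label -> channel -> 256 counts, plus per-region pixel
#' counts, in a stable key order.
#'
#' @param histograms Tibble from [region_color_histograms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histograms_json <- function(histograms, path) {
  regions <- sort(unique(histograms$region))
  out <- lapply(regions, function(rg) {
    per_chan <- lapply(c("R", "G", "B"), function(ch) {
      sub <- histograms[histograms$region == rg & histograms$channel == ch, ]
      as.integer(sub$count[order(sub$intensity)])
    })
    names(per_chan) <- c("R", "G", "B")
    c(per_chan, list(n_pixels = sum(per_chan$R)))
  })
  names(out) <- paste0("region_", regions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
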