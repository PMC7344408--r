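#' Sum three quantized MSB planes into a 4-level segmentation map
#'
#' The pointwise sum of the three filtered one-bit planes takes values 0--3:
#' level 3 marks pixels bright in all three channels (skin), level 0 marks the
#' darkest pixels (lesion core or the field outside the dermoscope inspection
#' area), and levels 1--2 the transition regions.
#'
#' @param p_r,p_g,p_b Integer 0/1 matrices of identical shape.
#' @return Integer matrix with values in 0--3.
#' @export
sum_planes <- function(p_r, p_g, p_b) {
  assert_binary_matrix(p_r, "p_r")
  assert_binary_matrix(p_g, "p_g")
  assert_binary_matrix(p_b, "p_b")
  assert_same_shape(p_r, p_g, "planes")
  assert_same_shape(p_r, p_b, "planes")
  p_r + p_g + p_b
}

#' Segmentation configuration
#'
#' Tunable parameters of the pipeline. The defaults are the validated
#' configuration: most significant bit plane, lesion defined as levels <= 2
#' (any pixel lacking the MSB in at least one channel — dermoscopic lesions
#' are darker than the surrounding skin, making level 3 the skin class),
#' majority-vote threshold 0.5, and all mask postprocessing steps enabled.
#'
#' @param bit_index Bit plane used for segmentation, 0--7 (default 7, the
#'   MSB; lower planes are an exploratory hook only).
#' @param lesion_level_max Highest level counted as lesion candidate, 0--2
#'   (default 2).
#' @param quantize_threshold One-bit re-quantization threshold in (0, 1)
#'   (default 0.5).
#' @param exclude_corner_components Drop candidate components touching any
#'   image corner (dark vignette outside the inspection area). Default `TRUE`.
#' @param keep_largest_component Keep only the largest remaining candidate
#'   component. Default `TRUE`.
#' @param fill_holes Fill interior holes of the selected component.
#'   Default `TRUE`.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(bit_index = 7L,
                                lesion_level_max = 2L,
                                quantize_threshold = 0.5,
                                exclude_corner_components = TRUE,
                                keep_largest_component = TRUE,
                                fill_holes = TRUE) {
  if (bit_index != floor(bit_index) || bit_index < 0 || bit_index > 7) {
    stop("`bit_index` must be an integer in [0, 7]", call. = FALSE)
  }
  if (lesion_level_max != floor(lesion_level_max) ||
      lesion_level_max < 0 || lesion_level_max > 2) {
    stop("`lesion_level_max` must be an integer in [0, 2]", call. = FALSE)
  }
  if (quantize_threshold <= 0 || quantize_threshold >= 1) {
    stop("`quantize_threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(
      bit_index = as.integer(bit_index),
      lesion_level_max = as.integer(lesion_level_max),
      quantize_threshold = as.numeric(quantize_threshold),
      exclude_corner_components = isTRUE(exclude_corner_components),
      keep_largest_component = isTRUE(keep_largest_component),
      fill_holes = isTRUE(fill_holes)
    ),
    class = "segmentation_config"
  )
}

#' @export
print.segmentation_config <- function(x, ...) {
  cat("<segmentation_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Extract the lesion mask from a 4-level segmentation map
#'
#' Candidate lesion pixels are those with level `<= lesion_level_max`. The
#' candidate set is then postprocessed according to the configuration flags:
#' 8-connected candidate components touching any image corner are discarded
#' (they belong to the dark field outside the dermoscope inspection area, not
#' to the lesion); the largest remaining component by pixel count is kept;
#' interior holes are filled (4-connected background components not reaching
#' the image border). Degenerate inputs yield an all-zero mask.
#'
#' @param levels Integer matrix with values in 0--3.
#' @param config A [segmentation_config()].
#' @return Integer 0/1 lesion mask.
#' @export
lesion_mask_from_levels <- function(levels, config = segmentation_config()) {
  if (!is.matrix(levels) || !all(levels %in% 0:3)) {
    stop("`levels` must be a matrix with values in 0..3", call. = FALSE)
  }
  cand <- matrix(as.integer(levels <= config$lesion_level_max),
                 nrow = nrow(levels))
  if (!any(cand == 1L)) return(cand)

  if (config$exclude_corner_components) {
    lab <- label_components(cand, connectivity = 8L)
    h <- nrow(cand)
    w <- ncol(cand)
    corner_labels <- unique(lab[cbind(c(1L, 1L, h, h), c(1L, w, 1L, w))])
    corner_labels <- corner_labels[corner_labels > 0L]
    if (length(corner_labels)) cand[lab %in% corner_labels] <- 0L
    if (!any(cand == 1L)) return(cand)
  }

  if (config$keep_largest_component) {
    lab <- label_components(cand, connectivity = 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes) # ties: smallest label, deterministic
    cand[] <- as.integer(lab == keep)
  }

  if (config$fill_holes) cand <- fill_holes(cand)
  cand
}
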