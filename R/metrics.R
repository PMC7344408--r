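#' Pixel-level confusion counts between predicted and true lesion masks
#'
#' TP counts lesion pixels predicted as lesion, TN non-lesion pixels predicted
#' as non-lesion, FP non-lesion pixels predicted as lesion, FN lesion pixels
#' predicted as non-lesion; the four always sum to the pixel count.
#'
#' @param predicted Integer 0/1 predicted lesion mask.
#' @param truth Integer 0/1 ground-truth mask of identical shape.
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  assert_binary_matrix(predicted, "predicted")
  assert_binary_matrix(truth, "truth")
  assert_same_shape(predicted, truth, "masks")
  p <- predicted == 1L
  t <- truth == 1L
  tibble::tibble(
    tp = sum(p & t),
    fp = sum(p & !t),
    tn = sum(!p & !t),
    fn = sum(!p & t)
  )
}

#' Pixel-level segmentation accuracy
#'
#' `(TP + TN) / (TP + FP + TN + FN)`: the fraction of pixels on which the
#' predicted mask agrees with the expert ground truth.
#'
#' @param counts Confusion counts: a one-row data frame or named list with
#'   `tp`, `fp`, `tn`, `fn` (see [confusion_counts()]).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (length(total) != 1L || is.na(total) || total <= 0) {
    stop("accuracy undefined: confusion counts sum to zero", call. = FALSE)
  }
  (counts$tp + counts$tn) / total
}

#' All per-mask metrics for one predicted/truth pair
#'
#' Accuracy is the headline quantity; Dice, Jaccard, sensitivity and
#' specificity are reported alongside as standard companions. Overlap metrics
#' are `NA` when undefined (empty union / no positives / no negatives).
#'
#' @inheritParams confusion_counts
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`, `dice`,
#'   `jaccard`, `sensitivity`, `specificity`.
#' @export
mask_metrics <- function(predicted, truth) {
  cc <- confusion_counts(predicted, truth)
  den_dice <- 2 * cc$tp + cc$fp + cc$fn
  den_jac <- cc$tp + cc$fp + cc$fn
  dplyr::mutate(
    cc,
    accuracy = accuracy(cc),
    dice = ifelse(den_dice > 0, 2 * cc$tp / den_dice, NA_real_),
    jaccard = ifelse(den_jac > 0, cc$tp / den_jac, NA_real_),
    sensitivity = ifelse(cc$tp + cc$fn > 0, cc$tp / (cc$tp + cc$fn), NA_real_),
    specificity = ifelse(cc$tn + cc$fp > 0, cc$tn / (cc$tn + cc$fp), NA_real_)
  )
}

#' Evaluate the segmentation pipeline over a dataset
#'
#' Runs [segment_lesion()] on every image, scores each predicted mask against
#' its expert ground truth, and aggregates by the unweighted per-image mean
#' (common segmentation-benchmark practice; images are not pooled by pixel
#' count). Images whose segmentation fails are recorded, skipped and counted.
#'
#' @param pairs A list of cases, each a list with elements `image`
#'   ([rgb_image()]), `truth` (0/1 matrix) and `id` (identifier string); the
#'   format returned by [generate_suite()] or [load_dataset_pairs()].
#' @param config A [segmentation_config()].
#' @return A `lesion_eval` object: list with `per_image` (tibble of id,
#'   confusion counts and metrics), `mean_accuracy`, `n_images`, `n_skipped`,
#'   `skipped_ids`.
#' @export
evaluate_dataset <- function(pairs, config = segmentation_config()) {
  if (!is.list(pairs) || length(pairs) < 1L) {
    stop("`pairs` must be a non-empty list of (image, truth, id) cases",
         call. = FALSE)
  }
  rows <- list()
  skipped <- character(0)
  for (case in pairs) {
    id <- if (!is.null(case$id)) case$id else sprintf("case_%03d", length(rows))
    res <- tryCatch({
      assert_same_shape(unclass(rgb_image(case$image)), case$truth,
                        "image and truth mask")
      seg <- segment_lesion(case$image, config)
      dplyr::bind_cols(tibble::tibble(id = id),
                       mask_metrics(seg$mask, case$truth))
    }, error = function(e) {
      warning(sprintf("skipping '%s': %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, id) else rows[[length(rows) + 1L]] <- res
  }
  per_image <- dplyr::bind_rows(rows)
  structure(
    list(
      per_image = per_image,
      mean_accuracy = if (nrow(per_image)) mean(per_image$accuracy) else NA_real_,
      n_images = nrow(per_image),
      n_skipped = length(skipped),
      skipped_ids = skipped
    ),
    class = "lesion_eval"
  )
}

#' @export
print.lesion_eval <- function(x, ...) {
  cat(sprintf("<lesion_eval> %d images (%d skipped); mean accuracy %.4f\n",
              x$n_images, x$n_skipped, x$mean_accuracy))
  invisible(x)
}

#' @rdname evaluate_dataset
#' @param x A `lesion_eval` object.
#' @param ... Unused.
#' @return `tidy()`: the per-image metrics tibble.
#' @exportS3Method
tidy.lesion_eval <- function(x, ...) x$per_image

#' @rdname evaluate_dataset
#' @return `glance()`: a one-row tibble with image counts and the mean of
#'   each metric over images.
#' @exportS3Method
glance.lesion_eval <- function(x, ...) {
  tibble::tibble(
    n_images = x$n_images,
    n_skipped = x$n_skipped,
    mean_accuracy = x$mean_accuracy,
    mean_dice = mean(x$per_image$dice, na.rm = TRUE),
    mean_jaccard = mean(x$per_image$jaccard, na.rm = TRUE),
    mean_sensitivity = mean(x$per_image$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$per_image$specificity, na.rm = TRUE)
  )
}

#' Pair images with ground-truth masks from a directory layout
#'
#' Supports parallel image/mask directories: every readable image in
#' `image_dir` is paired with `<stem><mask_suffix>.<ext>` in `mask_dir`
#' (default suffix `"_lesion"`, the PH2 convention). Images with no mask file
#' are skipped with a warning.
#'
#' @param image_dir Directory of dermoscopic images (png/jpg/jpeg/tif/tiff).
#' @param mask_dir Directory of mask images (defaults to `image_dir`).
#' @param mask_suffix Filename suffix distinguishing masks (default
#'   `"_lesion"`).
#' @return A list of cases suitable for [evaluate_dataset()].
#' @export
load_dataset_pairs <- function(image_dir, mask_dir = image_dir,
                               mask_suffix = "_lesion") {
  exts <- "\\.(png|jpg|jpeg|tif|tiff)$"
  imgs <- list.files(image_dir, pattern = exts, ignore.case = TRUE)
  imgs <- imgs[!grepl(paste0(mask_suffix, "\\."), imgs, fixed = FALSE)]
  if (!length(imgs)) stop(sprintf("no images found in '%s'", image_dir), call. = FALSE)
  pairs <- list()
  for (f in sort(imgs)) {
    stem <- tools::file_path_sans_ext(f)
    hits <- list.files(mask_dir,
                       pattern = paste0("^", stem, mask_suffix, exts),
                       ignore.case = TRUE)
    if (!length(hits)) {
      warning(sprintf("no mask for image '%s'; skipped", f), call. = FALSE)
      next
    }
    pairs[[length(pairs) + 1L]] <- list(
      image = load_rgb_image(file.path(image_dir, f)),
      truth = load_mask(file.path(mask_dir, hits[1L])),
      id = stem
    )
  }
  if (!length(pairs)) stop("no image/mask pairs could be formed", call. = FALSE)
  pairs
}
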