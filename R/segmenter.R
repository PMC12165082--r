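# Single-cell segmentation to a uniform background: a per-pixel colour
# classifier (linear discriminant on RGB) trained on crops with truth
# masks. Inference standardizes crops to 224 x 224, predicts a mask, keeps
# the largest component, fills holes, and maps back to crop resolution.

#' Train the cell/background segmenter
#'
#' @param crops List of RGB crop arrays.
#' @param masks List of logical truth masks (same shapes as `crops`).
#' @param pixels_per_crop Pixels sampled from each crop for the fit.
#' @param seed Seed for pixel sampling.
#' @return An `etc_segmenter` with the pixel classifier and validation Dice
#'   (computed on the training crops; pass held-out crops to
#'   [segmenter_dice()] for an honest estimate).
#' @export
train_segmenter <- function(crops, masks, pixels_per_crop = 600, seed = 1) {
  stopifnot(length(crops) == length(masks), length(crops) >= 1)
  samp <- with_seed(seed, {
    purrr::map2_dfr(crops, masks, function(img, mask) {
      n <- length(mask)
      idx <- sample(n, min(pixels_per_crop, n))
      tibble::tibble(
        r = img[, , 1][idx], g = img[, , 2][idx], b = img[, , 3][idx],
        cell = as.integer(mask[idx])
      )
    })
  })
  if (length(unique(samp$cell)) < 2) stop("need both cell and background pixels")
  fit <- suppressWarnings(MASS::lda(cell ~ r + g + b, data = samp))
  structure(list(model = fit), class = "etc_segmenter")
}

#' Segment a cell crop
#'
#' @param crop RGB crop array.
#' @param segmenter An `etc_segmenter` from [train_segmenter()].
#' @param min_area Minimum mask area in 224 x 224 pixels; below it the crop
#'   is flagged empty.
#' @return A list: `mask` (logical, crop resolution), `empty` (flag: no
#'   cell found; such crops are not passed downstream).
#' @export
segment_cell <- function(crop, segmenter, min_area = 30) {
  if (!inherits(segmenter, "etc_segmenter")) stop("untrained segmenter")
  std <- resize_raster(crop, 224L, 224L)
  px <- data.frame(r = as.vector(std[, , 1]), g = as.vector(std[, , 2]),
                   b = as.vector(std[, , 3]))
  post <- stats::predict(segmenter$model, newdata = px)$posterior[, "1"]
  m <- matrix(post > 0.5, 224L, 224L)
  if (sum(m) < min_area) {
    return(list(mask = matrix(FALSE, nrow(crop), ncol(crop)), empty = TRUE))
  }
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  m <- lab == which.max(sizes)
  m <- EBImage::fillHull(m) > 0
  full <- resize_raster(m, dim(crop)[1], dim(crop)[2])
  list(mask = full, empty = FALSE)
}

#' Mean Dice score of the segmenter on crops with truth masks
#'
#' @param segmenter An `etc_segmenter`.
#' @param crops,masks Held-out crops and truth masks.
#' @return Mean Dice coefficient.
#' @export
segmenter_dice <- function(segmenter, crops, masks) {
  mean(purrr::map2_dbl(crops, masks, function(img, truth) {
    pred <- segment_cell(img, segmenter)$mask
    denom <- sum(pred) + sum(truth)
    if (denom == 0) return(1)
    2 * sum(pred & truth) / denom
  }))
}

#' Replace background pixels with a uniform fill colour
#'
#' Idempotent: applying it twice equals applying it once.
#'
#' @param crop RGB crop array.
#' @param mask Logical cell mask (crop resolution).
#' @param fill RGB fill colour (defaults to the palette background).
#' @return The crop with all outside-mask pixels set to `fill`.
#' @export
remove_background <- function(crop, mask, fill = default_palette()$background) {
  for (c in 1:3) {
    pane <- crop[, , c]
    pane[!mask] <- fill[c]
    crop[, , c] <- pane
  }
  crop
}
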