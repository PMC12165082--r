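# Dual-channel malignancy classification: morphometric features of the
# segmented cell feed a logistic model per size channel, with the operating
# threshold calibrated to a target specificity on the validation split.

#' Morphometric features of a segmented cell
#'
#' Computed on the background-removed channel crop and its mask: cell area,
#' nucleus-to-cell area ratio, contour irregularity (perimeter^2 / 4 pi
#' area), chromatin texture (intensity SD inside the nucleus), and colour
#' summaries.
#'
#' @param image Channel crop (RGB array, background removed or not).
#' @param mask Logical cell mask in the same crop.
#' @return A one-row tibble of features.
#' @export
cell_features <- function(image, mask) {
  area <- sum(mask)
  if (area == 0) stop("empty mask")
  pal <- default_palette()
  nd <- color_distance(image, pal$nucleus)
  cd <- color_distance(image, pal$cytoplasm)
  nuc <- mask & (nd < cd)
  intens <- raster_intensity(image)
  bb <- mask_bbox(mask)
  inner <- mask
  inner[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] <-
    mask[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] &
    mask[1:(nrow(mask) - 2), 2:(ncol(mask) - 1)] &
    mask[3:nrow(mask), 2:(ncol(mask) - 1)] &
    mask[2:(nrow(mask) - 1), 1:(ncol(mask) - 2)] &
    mask[2:(nrow(mask) - 1), 3:ncol(mask)]
  perimeter <- sum(mask & !inner)
  tibble::tibble(
    area = area,
    long_side = max(bb$w, bb$h),
    ncr = sum(nuc) / area,
    irregularity = perimeter^2 / (4 * pi * area),
    texture = if (sum(nuc) > 1) stats::sd(intens[nuc]) else 0,
    mean_int = mean(intens[mask]),
    solidity = area / (bb$w * bb$h)
  )
}

#' Calibrate the operating threshold to a target specificity
#'
#' Among candidate thresholds (the unique scores, midpoints between
#' consecutive unique scores, and one value above the maximum), returns the
#' smallest at which specificity (fraction of benign scores below the
#' threshold, with calls made at score >= threshold) reaches `spec_min`.
#' When even the largest candidate fails, the threshold is set just above
#' the maximum score with a warning.
#'
#' @param scores Numeric malignancy scores.
#' @param labels Logical (or 0/1) truth: TRUE = malignant.
#' @param spec_min Target specificity (default 0.998).
#' @return The threshold, with attribute `specificity` (achieved on the
#'   calibration data) and `sensitivity`.
#' @export
calibrate_threshold <- function(scores, labels, spec_min = 0.998) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("calibration data needs both classes")
  u <- sort(unique(scores))
  cands <- sort(unique(c(u, u[-length(u)] + diff(u) / 2)))
  neg <- scores[!labels]
  pos <- scores[labels]
  spec_at <- vapply(cands, function(t) mean(neg < t), numeric(1))
  ok <- which(spec_at >= spec_min)
  if (length(ok) == 0) {
    warning("target specificity unattainable below the maximum score; ",
            "threshold set above all scores (zero sensitivity)")
    thr <- max(scores) + 1e-6
  } else {
    thr <- cands[ok[1]]
  }
  attr(thr, "specificity") <- mean(neg < thr)
  attr(thr, "sensitivity") <- mean(pos >= thr)
  thr
}

#' Train one channel's malignancy classifier
#'
#' Splits the labelled cells 7:2:1 (train/validation/test), fits a logistic
#' model on morphometric features, calibrates the operating threshold to
#' `spec_min` specificity on the validation split, and reports held-out
#' test AUC.
#'
#' @param cells A tibble of [cell_features()] columns plus a logical
#'   `malignant` column.
#' @param channel `"large"` or `"small"` (recorded, and used to drop the
#'   degenerate size feature spread within a channel).
#' @param split Train/validation/test fractions (must sum to 1).
#' @param spec_min Target specificity for threshold calibration.
#' @param seed Split seed.
#' @return An `etc_classifier` with `model`, `threshold`, `channel`, and
#'   evaluation tibbles `validation` and `test` (AUC, sensitivity,
#'   specificity at the calibrated threshold).
#' @export
train_channel_classifier <- function(cells, channel = c("large", "small"),
                                     split = c(0.7, 0.2, 0.1),
                                     spec_min = 0.998, seed = 1) {
  channel <- match.arg(channel)
  stopifnot(abs(sum(split) - 1) < 1e-8, "malignant" %in% names(cells))
  n <- nrow(cells)
  idx <- with_seed(seed, sample(n))
  n_tr <- round(n * split[1]); n_va <- round(n * split[2])
  tr <- cells[idx[seq_len(n_tr)], ]
  va <- cells[idx[n_tr + seq_len(n_va)], ]
  te <- cells[idx[(n_tr + n_va + 1):n], ]
  if (length(unique(tr$malignant)) < 2) stop("training split has one class")
  form <- malignant ~ ncr + irregularity + texture + mean_int + solidity +
    log(area)
  # linear discriminant on the morphometric features; the score is the
  # logistic of the standardized discriminant projection, which stays
  # continuous even when the classes separate (a saturated probability
  # would make specificity calibration degenerate)
  fit <- suppressWarnings(MASS::lda(form, data = tr))
  proj <- function(d) {
    unname(suppressWarnings(stats::predict(fit, newdata = d)$x[, 1]))
  }
  ptr <- proj(tr)
  flip <- if (mean(ptr[tr$malignant]) < mean(ptr[!tr$malignant])) -1 else 1
  centre <- mean(ptr); scale <- stats::sd(ptr)
  scorer <- list(fit = fit, flip = flip, centre = centre, scale = scale)
  score <- function(d) score_features(scorer, d)
  va_scores <- score(va)
  thr <- calibrate_threshold(va_scores, va$malignant, spec_min)
  eval_split <- function(d) {
    s <- score(d)
    tibble::tibble(
      auc = if (length(unique(d$malignant)) == 2) {
        unname(roc_auc(s, d$malignant)$auc)
      } else NA_real_,
      sensitivity = mean(s[d$malignant] >= thr),
      specificity = mean(s[!d$malignant] < thr),
      n = nrow(d)
    )
  }
  structure(
    list(model = scorer, threshold = as.numeric(thr), channel = channel,
         spec_min = spec_min,
         validation = eval_split(va), test = eval_split(te)),
    class = "etc_classifier"
  )
}

# Malignancy score of feature rows under a fitted scorer: logistic of the
# standardized (and sign-fixed) discriminant projection.
score_features <- function(scorer, d) {
  p <- unname(suppressWarnings(stats::predict(scorer$fit, newdata = d)$x[, 1]))
  stats::plogis(scorer$flip * (p - scorer$centre) / scorer$scale)
}

#' Score one segmented cell with its channel classifier
#'
#' @param features A one-row tibble from [cell_features()].
#' @param classifier An `etc_classifier`.
#' @return A list: `score` (malignancy probability) and `call` (TRUE when
#'   score >= operating threshold).
#' @export
classify_cell <- function(features, classifier) {
  s <- score_features(classifier$model, features)
  list(score = s, call = s >= classifier$threshold)
}

#' @export
print.etc_classifier <- function(x, ...) {
  cat(sprintf(
    "%s-cell malignancy classifier: threshold %.4f (target specificity %.3f)\n",
    x$channel, x$threshold, x$spec_min))
  cat(sprintf("  test AUC %.3f, sensitivity %.3f, specificity %.3f (n=%d)\n",
              x$test$auc, x$test$sensitivity, x$test$specificity, x$test$n))
  invisible(x)
}
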