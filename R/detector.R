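# Cell-candidate detection: a learned background-colour model proposes
# foreground components, and a logistic box scorer assigns each candidate a
# confidence. Candidates then pass the confidence filter and NMS.

# Euclidean distance of every pixel from a reference colour.
color_distance <- function(img, color) {
  sqrt((img[, , 1] - color[1])^2 + (img[, , 2] - color[2])^2 +
         (img[, , 3] - color[3])^2)
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x) {
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = 257),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[length(cm)]
  between <- (mt * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Extract candidate components from a patch: returns a tibble of boxes with
# per-candidate features. `min_area` suppresses speckle.
extract_candidates <- function(patch, bg_color, dist_threshold, min_area = 40) {
  d <- color_distance(patch, bg_color)
  fg <- d > dist_threshold
  lab <- EBImage::bwlabel(fg)
  n <- max(lab)
  if (n == 0) return(empty_boxes())
  out <- vector("list", n)
  H <- nrow(fg); W <- ncol(fg)
  for (k in seq_len(n)) {
    mk <- lab == k
    area <- sum(mk)
    if (area < min_area) next
    bb <- mask_bbox(mk)
    edge <- bb$x == 0 || bb$y == 0 || bb$x + bb$w >= W || bb$y + bb$h >= H
    out[[k]] <- tibble::tibble(
      x = bb$x, y = bb$y, w = bb$w, h = bb$h,
      area = area, density = area / (bb$w * bb$h),
      mean_dist = mean(d[mk]), long_side = max(bb$w, bb$h),
      aspect = max(bb$w, bb$h) / min(bb$w, bb$h),
      edge = as.numeric(edge)
    )
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty_boxes() else out
}

empty_boxes <- function() {
  tibble::tibble(x = integer(0), y = integer(0), w = integer(0), h = integer(0),
                 area = numeric(0), density = numeric(0), mean_dist = numeric(0),
                 long_side = numeric(0), aspect = numeric(0), edge = numeric(0))
}

#' Train the cell-candidate detector
#'
#' Learns the slide background colour and an Otsu foreground threshold from
#' the training patches, then fits a logistic confidence model on candidate
#' features, with candidates matched to ground-truth boxes at IoU >= 0.5 as
#' positives. Deterministic given the seed.
#'
#' @param patches A tibble with list-columns `pixels` (1024 x 1024 arrays)
#'   and `boxes` (tibbles of ground-truth `x`, `y`, `w`, `h`).
#' @param val_fraction Fraction of patches held out for validation (split
#'   9:1 by default).
#' @param conf_min,iou_max Operating thresholds used when reporting
#'   validation recall/precision.
#' @param seed Seed for the split.
#' @return An `etc_detector` object with elements `bg_color`,
#'   `dist_threshold`, `model`, and `validation` (tibble with recall and
#'   precision at IoU 0.5).
#' @export
train_detector <- function(patches, val_fraction = 0.1, conf_min = 0.3,
                           iou_max = 0.5, seed = 1) {
  stopifnot(nrow(patches) >= 2, all(c("pixels", "boxes") %in% names(patches)))
  bg <- modal_border_color(patches$pixels[[1]])
  dsamp <- unlist(lapply(patches$pixels[seq_len(min(5, nrow(patches)))],
                         function(p) {
                           d <- color_distance(p, bg)
                           d[seq(1, length(d), by = 23)]
                         }))
  thr <- otsu_threshold(dsamp)

  n_val <- max(1, round(nrow(patches) * val_fraction))
  val_idx <- with_seed(seed, sample(nrow(patches), n_val))
  train_idx <- setdiff(seq_len(nrow(patches)), val_idx)

  harvest <- function(idx) {
    purrr::map_dfr(idx, function(i) {
      cand <- extract_candidates(patches$pixels[[i]], bg, thr)
      if (nrow(cand) == 0) return(cand)
      truth <- patches$boxes[[i]]
      cand$matched <- vapply(seq_len(nrow(cand)), function(r) {
        if (nrow(truth) == 0) return(0)
        as.numeric(any(vapply(seq_len(nrow(truth)),
                              function(t) iou(cand[r, ], truth[t, ]) >= 0.5,
                              logical(1))))
      }, numeric(1))
      cand$patch <- i
      cand
    })
  }
  tr <- harvest(train_idx)
  if (nrow(tr) == 0) stop("no candidates extracted from training patches")
  model <- if (length(unique(tr$matched)) < 2) NULL else {
    suppressWarnings(stats::glm(
      matched ~ log(area) + density + mean_dist + aspect + edge,
      family = stats::binomial(), data = tr
    ))
  }
  det <- structure(
    list(bg_color = bg, dist_threshold = thr, model = model,
         conf_min = conf_min, iou_max = iou_max),
    class = "etc_detector"
  )
  det$validation <- detector_validation(det, patches[val_idx, ])
  det
}

detector_validation <- function(det, patches) {
  hits <- 0L; truths <- 0L; preds <- 0L
  for (i in seq_len(nrow(patches))) {
    kept <- detect_cells(patches$pixels[[i]], det)
    truth <- patches$boxes[[i]]
    truths <- truths + nrow(truth)
    preds <- preds + nrow(kept)
    if (nrow(truth) > 0 && nrow(kept) > 0) {
      for (t in seq_len(nrow(truth))) {
        ious <- vapply(seq_len(nrow(kept)),
                       function(r) iou(kept[r, ], truth[t, ]), numeric(1))
        if (any(ious >= 0.5)) hits <- hits + 1L
      }
    }
  }
  tibble::tibble(
    recall = if (truths > 0) hits / truths else NA_real_,
    precision = if (preds > 0) hits / preds else NA_real_,
    n_truth = truths, n_pred = preds
  )
}

#' Detect cell candidates on a patch
#'
#' @param patch 1024 x 1024 RGB array (any size accepted).
#' @param detector An `etc_detector` from [train_detector()].
#' @param nms Apply the confidence filter + NMS (default TRUE).
#' @return A tibble of boxes with `confidence`.
#' @export
detect_cells <- function(patch, detector, nms = TRUE) {
  cand <- extract_candidates(patch, detector$bg_color, detector$dist_threshold)
  if (nrow(cand) == 0) {
    return(dplyr::mutate(cand, confidence = numeric(0)))
  }
  cand$confidence <- if (is.null(detector$model)) {
    rep(0.9, nrow(cand))
  } else {
    unname(suppressWarnings(
      stats::predict(detector$model, newdata = cand, type = "response")
    ))
  }
  if (nms) {
    nms_filter(cand, conf_min = detector$conf_min, iou_max = detector$iou_max)
  } else {
    cand
  }
}

#' @export
print.etc_detector <- function(x, ...) {
  cat("Cell-candidate detector: background colour (",
      paste(round(x$bg_color, 3), collapse = ", "),
      "), foreground threshold ", round(x$dist_threshold, 3), "\n", sep = "")
  if (!is.null(x$validation)) {
    cat(sprintf("  validation recall %.3f, precision %.3f (IoU 0.5)\n",
                x$validation$recall, x$validation$precision))
  }
  invisible(x)
}
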