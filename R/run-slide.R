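# The full imaging cascade on one slide: tile -> detect -> NMS -> crop ->
# QC -> segment -> route -> classify -> aggregate.

# Crop a box (with margin) out of the slide, padding at the edges.
crop_box <- function(wsi, box, margin = 6L,
                     fill = default_palette()$background) {
  x0 <- box$x - margin; y0 <- box$y - margin
  w <- box$w + 2 * margin; h <- box$h + 2 * margin
  out <- blank_raster(h, w, fill)
  src_x <- max(0, x0):min(dim(wsi)[2] - 1, x0 + w - 1)
  src_y <- max(0, y0):min(dim(wsi)[1] - 1, y0 + h - 1)
  out[src_y - y0 + 1, src_x - x0 + 1, ] <-
    wsi[src_y + 1, src_x + 1, , drop = FALSE]
  out
}

#' Run the imaging cascade on a whole-slide image
#'
#' Tiles the slide, detects candidates per patch, filters with confidence +
#' NMS, and passes each kept box through QC, segmentation, size routing and
#' the channel classifiers. Per-cell records carry full provenance; stage
#' counts are monotone non-increasing along the cascade. The ETC%
#' denominator is QC-passed cells.
#'
#' @param wsi RGB slide array.
#' @param models A list with `detector`, `qc`, `segmenter`, `large`,
#'   `small` (see [train_models()]).
#' @param cutoff Slide-call cutoff on ETC% (default 0.2).
#' @param slide_id Identifier for the output.
#' @return A `slide_run` list: `result` (one-row [SlideResult] tibble:
#'   slide_id, n_total_cells, n_etc, etc_percent, call), `records`
#'   (per-cell tibble), `stage_counts`.
#' @export
run_slide <- function(wsi, models, cutoff = 0.2, slide_id = "slide") {
  stopifnot(all(c("detector", "qc", "segmenter", "large", "small") %in%
                  names(models)))
  patches <- tile_wsi(wsi)
  boxes <- purrr::map_dfr(seq_len(nrow(patches)), function(i) {
    b <- detect_cells(patches$pixels[[i]], models$detector)
    if (nrow(b) == 0) return(b)
    b$x <- b$x + patches$ox[i]
    b$y <- b$y + patches$oy[i]
    b$patch_id <- patches$patch_id[i]
    b
  })
  n_detected <- nrow(boxes)
  records <- list()
  for (i in seq_len(nrow(boxes))) {
    box <- boxes[i, ]
    crop <- crop_box(wsi, box)
    verdict <- qc_classify(crop, models$qc)
    rec <- tibble::tibble(
      slide_id = slide_id, patch_id = box$patch_id,
      x = box$x, y = box$y, w = box$w, h = box$h,
      confidence = box$confidence,
      qc_category = verdict$category,
      qc_pass = verdict$category == "high_quality",
      segmented = FALSE, channel = NA_character_,
      score = NA_real_, call = FALSE
    )
    if (rec$qc_pass) {
      seg <- segment_cell(crop, models$segmenter)
      if (!seg$empty) {
        rec$segmented <- TRUE
        clean <- remove_background(crop, seg$mask)
        channel <- route_by_size(seg$mask)
        cc <- channel_crop(clean, seg$mask, channel)
        feats <- cell_features(cc$image, cc$mask)
        cls <- classify_cell(feats, models[[channel]])
        rec$channel <- channel
        rec$score <- cls$score
        rec$call <- cls$call
      }
    }
    records[[i]] <- rec
  }
  records <- if (length(records)) dplyr::bind_rows(records) else {
    tibble::tibble(slide_id = character(0), patch_id = integer(0),
                   x = integer(0), y = integer(0), w = integer(0),
                   h = integer(0), confidence = numeric(0),
                   qc_category = character(0), qc_pass = logical(0),
                   segmented = logical(0), channel = character(0),
                   score = numeric(0), call = logical(0))
  }
  n_total <- sum(records$qc_pass)
  n_etc <- sum(records$call)
  pct <- if (n_total > 0) etc_fraction(n_etc, n_total) else 0
  result <- tibble::tibble(
    slide_id = slide_id,
    n_total_cells = n_total,
    n_etc = n_etc,
    etc_percent = pct,
    call = n_total > 0 && slide_call(pct, cutoff) == "positive"
  )
  structure(
    list(result = result, records = records,
         stage_counts = tibble::tibble(
           detected = n_detected,
           qc_passed = n_total,
           segmented = sum(records$segmented),
           classified = sum(!is.na(records$score)),
           etc = n_etc
         )),
    class = "slide_run"
  )
}

#' @export
print.slide_run <- function(x, ...) {
  r <- x$result
  cat(sprintf("Slide %s: %d QC-passed cells, %d predicted ETCs (%.3f%%) -> %s\n",
              r$slide_id, r$n_total_cells, r$n_etc, r$etc_percent,
              ifelse(r$call, "positive", "negative")))
  invisible(x)
}

#' Generate synthetic training data and train all imaging models
#'
#' Renders annotated training patches for the detector, labelled crops for
#' the QC model, crops + truth masks for the segmenter, and labelled cell
#' batches for the two channel classifiers, then trains each stage.
#'
#' @param n_patches Training patches for the detector.
#' @param n_qc_per_class Crops per QC category.
#' @param n_seg Crops for the segmenter.
#' @param n_class_per_group Cells per (channel x label) group for the
#'   channel classifiers.
#' @param spec_min Target specificity for threshold calibration.
#' @param seed Seed.
#' @return A named list of trained models (`detector`, `qc`, `segmenter`,
#'   `large`, `small`).
#' @export
train_models <- function(n_patches = 24, n_qc_per_class = 30, n_seg = 40,
                         n_class_per_group = 150, spec_min = 0.998, seed = 1) {
  patches <- purrr::map(seq_len(n_patches), function(i) {
    sl <- render_slide(slide_spec(n_cells = 14, etc_fraction = 20,
                                  junk_fraction = 0.2, seed = seed * 100 + i))
    tibble::tibble(pixels = list(sl$wsi),
                   boxes = list(sl$annotations[, c("x", "y", "w", "h")]))
  })
  patches <- dplyr::bind_rows(patches)
  detector <- train_detector(patches, seed = seed)

  qc_crops <- list(); qc_labels <- character(0)
  k <- 0
  # high-quality crops span the malignant morphology range so strongly
  # atypical (dark, high nucleus fraction) cells are not rejected as debris
  effects <- seq(0.8, 1.6, length.out = max(n_qc_per_class, 2))
  for (cat in qc_categories()) {
    for (i in seq_len(n_qc_per_class)) {
      k <- k + 1
      obj <- if (cat == "high_quality") {
        render_cell(sample_cell_spec(i %% 2 == 0, seed = seed * 7919 + k,
                                     effect = effects[i]),
                    seed = seed * 104729 + k)
      } else {
        render_junk(cat, seed = seed * 104729 + k)
      }
      qc_crops[[k]] <- obj$image
      qc_labels[k] <- cat
    }
  }
  qc <- train_qc_model(qc_crops, qc_labels, detector, seed = seed)

  seg_crops <- list(); seg_masks <- list()
  for (i in seq_len(n_seg)) {
    cell <- render_cell(sample_cell_spec(i %% 2 == 0, seed = seed * 31 + i),
                        seed = seed * 37 + i)
    seg_crops[[i]] <- cell$image
    seg_masks[[i]] <- cell$mask
  }
  segmenter <- train_segmenter(seg_crops, seg_masks, seed = seed)

  # training cells go through the same segmentation + background removal +
  # channel-crop path as pipeline cells, so the classifiers see the feature
  # distribution they will be scored on
  channel_cells <- function(channel) {
    purrr::map_dfr(seq_len(2 * n_class_per_group), function(i) {
      mal <- i <= n_class_per_group
      s <- seed * 1e5 + i + ifelse(channel == "large", 0, 5e4)
      cell <- render_cell(sample_cell_spec(mal, size_class = channel, seed = s),
                          seed = s + 1)
      seg <- segment_cell(cell$image, segmenter)
      if (seg$empty) return(NULL)
      clean <- remove_background(cell$image, seg$mask)
      cc <- channel_crop(clean, seg$mask, route_by_size(seg$mask))
      f <- cell_features(cc$image, cc$mask)
      f$malignant <- mal
      f
    })
  }
  large <- train_channel_classifier(channel_cells("large"), "large",
                                    spec_min = spec_min, seed = seed)
  small <- train_channel_classifier(channel_cells("small"), "small",
                                    spec_min = spec_min, seed = seed)
  list(detector = detector, qc = qc, segmenter = segmenter,
       large = large, small = small)
}
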