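# Geometry of the imaging arm: tiling, IoU, non-maximum suppression, and
# size routing. Boxes are (x, y, w, h) in pixels, 0-based, half-open.

#' Tile a whole-slide image into 1024 x 1024 patches
#'
#' Ceil-grid coverage in deterministic row-major order; right/bottom
#' remainder patches are padded with the background colour and flagged with
#' their pad extent.
#'
#' @param wsi RGB array (h x w x 3).
#' @param patch_size Patch side in pixels (default 1024).
#' @param pad_color Background fill for padded patches; defaults to the
#'   modal border colour of the slide.
#' @return A tibble with columns `patch_id`, `ox`, `oy` (global 0-based
#'   offsets), `pad_x`, `pad_y` (pad extents in px), and a list-column
#'   `pixels`.
#' @export
tile_wsi <- function(wsi, patch_size = 1024L, pad_color = NULL) {
  d <- dim(wsi)
  if (is.null(d) || d[1] < 1 || d[2] < 1) stop("empty raster")
  if (is.null(pad_color)) pad_color <- modal_border_color(wsi)
  nrows <- ceiling(d[1] / patch_size)
  ncols <- ceiling(d[2] / patch_size)
  out <- list()
  k <- 0L
  for (r in seq_len(nrows)) {
    for (cc in seq_len(ncols)) {
      k <- k + 1L
      oy <- (r - 1L) * patch_size
      ox <- (cc - 1L) * patch_size
      ylen <- min(patch_size, d[1] - oy)
      xlen <- min(patch_size, d[2] - ox)
      patch <- blank_raster(patch_size, patch_size, pad_color)
      patch[seq_len(ylen), seq_len(xlen), ] <-
        wsi[oy + seq_len(ylen), ox + seq_len(xlen), , drop = FALSE]
      out[[k]] <- tibble::tibble(
        patch_id = k, ox = ox, oy = oy,
        pad_x = patch_size - xlen, pad_y = patch_size - ylen,
        pixels = list(patch)
      )
    }
  }
  dplyr::bind_rows(out)
}

# Most common colour on the 1-px border of the slide (quantized to 1/255).
modal_border_color <- function(wsi) {
  d <- dim(wsi)
  idx <- rbind(
    cbind(1, seq_len(d[2])), cbind(d[1], seq_len(d[2])),
    cbind(seq_len(d[1]), 1), cbind(seq_len(d[1]), d[2])
  )
  cols <- vapply(1:3, function(c) wsi[cbind(idx, c)], numeric(nrow(idx)))
  key <- apply(round(cols * 255), 1, paste, collapse = ",")
  best <- names(sort(table(key), decreasing = TRUE))[1]
  as.numeric(strsplit(best, ",", fixed = TRUE)[[1]]) / 255
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes as `c(x, y, w, h)` (or lists/1-row data frames with
#'   those names), 0-based half-open pixels.
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  if (a["w"] <= 0 || a["h"] <= 0 || b["w"] <= 0 || b["h"] <= 0) {
    stop("degenerate zero-area box")
  }
  ix <- max(0, min(a["x"] + a["w"], b["x"] + b["w"]) - max(a["x"], b["x"]))
  iy <- max(0, min(a["y"] + a["h"], b["y"] + b["h"]) - max(a["y"], b["y"]))
  inter <- ix * iy
  uni <- a["w"] * a["h"] + b["w"] * b["h"] - inter
  unname(inter / uni)
}

as_box <- function(b) {
  if (is.numeric(b) && length(b) == 4 && is.null(names(b))) {
    names(b) <- c("x", "y", "w", "h")
  }
  b <- unlist(b[c("x", "y", "w", "h")])
  stopifnot(length(b) == 4, !any(is.na(b)))
  b
}

#' Filter detections by confidence and non-maximum suppression
#'
#' Drops boxes with confidence at or below `conf_min`, then greedily keeps
#' the highest-confidence remaining box and suppresses any box whose IoU
#' with a kept box exceeds `iou_max`. The output has pairwise IoU at or
#' below `iou_max`.
#'
#' @param boxes A tibble with columns `x`, `y`, `w`, `h`, `confidence`.
#' @param conf_min Confidence threshold (exclusive; default 0.3).
#' @param iou_max Suppression threshold (exclusive; default 0.5).
#' @return The kept rows, in descending confidence order.
#' @export
nms_filter <- function(boxes, conf_min = 0.3, iou_max = 0.5) {
  stopifnot(all(c("x", "y", "w", "h", "confidence") %in% names(boxes)))
  boxes <- boxes[boxes$confidence > conf_min, , drop = FALSE]
  if (nrow(boxes) == 0) return(boxes)
  ord <- order(boxes$confidence, decreasing = TRUE)
  boxes <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    ok <- TRUE
    if (any(keep)) {
      for (j in which(keep)) {
        if (iou(boxes[i, ], boxes[j, ]) > iou_max) {
          ok <- FALSE
          break
        }
      }
    }
    keep[i] <- ok
  }
  boxes[keep, , drop = FALSE]
}

#' Route a segmented cell to the large or small channel
#'
#' The longer side of the mask's bounding box decides: above `boundary`
#' pixels goes to the large channel (254 x 254 crop), otherwise small
#' (90 x 90). Cells exactly at the boundary go small.
#'
#' @param mask Logical matrix (cell mask in the crop).
#' @param boundary Routing boundary in pixels (default 90).
#' @return `"large"` or `"small"`.
#' @export
route_by_size <- function(mask, boundary = 90) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("empty mask cannot be routed")
  if (max(bb$w, bb$h) > boundary) "large" else "small"
}

# Standardize a crop to its channel size (centre crop or pad with fill).
channel_crop <- function(img, mask, channel, fill = default_palette()$background) {
  S <- if (channel == "large") 254L else 90L
  bb <- mask_bbox(mask)
  cx <- bb$x + bb$w / 2
  cy <- bb$y + bb$h / 2
  out <- blank_raster(S, S, fill)
  mout <- matrix(FALSE, S, S)
  x0 <- round(cx - S / 2)
  y0 <- round(cy - S / 2)
  src_x <- pmax(1, x0 + 1):pmin(ncol(mask), x0 + S)
  src_y <- pmax(1, y0 + 1):pmin(nrow(mask), y0 + S)
  dst_x <- src_x - x0
  dst_y <- src_y - y0
  ok_x <- dst_x >= 1 & dst_x <= S
  ok_y <- dst_y >= 1 & dst_y <= S
  out[dst_y[ok_y], dst_x[ok_x], ] <- img[src_y[ok_y], src_x[ok_x], , drop = FALSE]
  mout[dst_y[ok_y], dst_x[ok_x]] <- mask[src_y[ok_y], src_x[ok_x]]
  list(image = out, mask = mout)
}
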