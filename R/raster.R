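# Raster helpers. Images are numeric arrays h x w x 3 with values in [0, 1];
# pixel (x, y) is array element [y + 1, x + 1, ] (x right, y down, 0-based).

blank_raster <- function(h, w, color = c(0.92, 0.93, 0.95)) {
  array(rep(color, each = h * w), dim = c(h, w, 3))
}

#' Nearest-neighbour resize of an image or mask
#'
#' @param img A h x w x 3 array or a 2-D matrix (mask).
#' @param h,w Target size in pixels.
#' @return Resized array/matrix.
#' @export
resize_raster <- function(img, h, w) {
  d <- dim(img)
  ri <- pmin(pmax(round((seq_len(h) - 0.5) * d[1] / h + 0.5), 1), d[1])
  ci <- pmin(pmax(round((seq_len(w) - 0.5) * d[2] / w + 0.5), 1), d[2])
  if (length(d) == 3) img[ri, ci, , drop = FALSE] else img[ri, ci, drop = FALSE]
}

# Paste `crop` onto `canvas` at top-left pixel (x0, y0) (0-based), writing
# only where `mask` is TRUE. Clips at canvas edges.
composite_raster <- function(canvas, crop, mask, x0, y0) {
  ch <- dim(crop)[1]; cw <- dim(crop)[2]
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  ys <- (y0 + 1):(y0 + ch); xs <- (x0 + 1):(x0 + cw)
  keep_y <- ys >= 1 & ys <= H; keep_x <- xs >= 1 & xs <= W
  if (!any(keep_y) || !any(keep_x)) return(canvas)
  sub_mask <- mask[keep_y, keep_x, drop = FALSE]
  for (c in 1:3) {
    pane <- canvas[ys[keep_y], xs[keep_x], c]
    src <- crop[keep_y, keep_x, c]
    pane[sub_mask] <- src[sub_mask]
    canvas[ys[keep_y], xs[keep_x], c] <- pane
  }
  canvas
}

# Tight bounding box of a mask in local 0-based half-open pixel coordinates;
# NULL for an empty mask.
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0) return(NULL)
  list(x = min(cols) - 1L, y = min(rows) - 1L,
       w = max(cols) - min(cols) + 1L, h = max(rows) - min(rows) + 1L)
}

# Separable Gaussian blur, applied per channel.
blur_raster <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    pad <- function(mm, n, side) {
      if (side == "top") rbind(mm[rep(1, n), , drop = FALSE], mm)
      else rbind(mm, mm[rep(nrow(mm), n), , drop = FALSE])
    }
    m2 <- pad(pad(m, r, "top"), r, "bottom")
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * m2[i:(i + nrow(m) - 1), , drop = FALSE]
    out
  }
  for (c in 1:3) {
    img[, , c] <- t(blur1(t(blur1(img[, , c]))))
  }
  img
}

# Mean intensity (luma) of an RGB raster.
raster_intensity <- function(img) {
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

# Variance of the discrete Laplacian of the intensity image: a sharpness
# measure (low for blurred crops).
laplacian_variance <- function(img) {
  g <- raster_intensity(img)
  n <- nrow(g); m <- ncol(g)
  if (n < 3 || m < 3) return(0)
  lap <- g[2:(n - 1), 2:(m - 1)] * -4 +
    g[1:(n - 2), 2:(m - 1)] + g[3:n, 2:(m - 1)] +
    g[2:(n - 1), 1:(m - 2)] + g[2:(n - 1), 3:m]
  stats::var(as.vector(lap))
}

#' Run-length encode a binary mask
#'
#' Column-major runs over the flattened mask, starting with the length of
#' the initial run of zeros: `"h,w:n0 n1 n0 n1 ..."`.
#' @param mask Logical matrix.
#' @return A single string.
#' @export
rle_encode <- function(mask) {
  r <- rle(as.integer(mask))
  if (length(r$values) > 0 && r$values[1] == 1L) {
    r$lengths <- c(0L, r$lengths)
  }
  paste0(nrow(mask), ",", ncol(mask), ":", paste(r$lengths, collapse = " "))
}

#' @rdname rle_encode
#' @param x An RLE string from [rle_encode()].
#' @export
rle_decode <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  dims <- as.integer(strsplit(parts[1], ",", fixed = TRUE)[[1]])
  lens <- as.integer(strsplit(parts[2], " ", fixed = TRUE)[[1]])
  vals <- rep(c(0L, 1L), length.out = length(lens))
  matrix(as.logical(rep(vals, lens)), nrow = dims[1], ncol = dims[2])
}

#' Write / read an RGB raster as PNG
#' @param img h x w x 3 array in \[0,1\].
#' @param path File path.
#' @export
write_raster_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_raster_png
#' @export
read_raster_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
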