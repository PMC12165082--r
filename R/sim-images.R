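# Synthetic Pap-like cytology rendering: single cells, junk objects, and
# whole slides composed of 1024 x 1024 patches with ground-truth boxes,
# masks and labels.

#' Default Pap-like stain palette
#'
#' RGB triples in \[0,1\] for nucleus, cytoplasm, background and debris.
#' @export
default_palette <- function() {
  list(
    nucleus = c(0.28, 0.22, 0.48),
    cytoplasm = c(0.58, 0.76, 0.78),
    background = c(0.92, 0.93, 0.95),
    impurity = c(0.45, 0.35, 0.22)
  )
}

#' Specify a single rendered cell
#'
#' @param size_class `"large"` or `"small"` (254 px / 90 px crops).
#' @param malignant Logical.
#' @param ncr Nucleus-to-cytoplasm (cell) area ratio in (0, 1).
#' @param irregularity Contour irregularity amplitude (>= 0).
#' @param texture Chromatin texture amplitude (>= 0).
#' @param palette Stain palette, see [default_palette()].
#' @return A `cell_render_spec`.
#' @export
cell_render_spec <- function(size_class = c("large", "small"), malignant = FALSE,
                             ncr = 0.3, irregularity = 0.05, texture = 0.05,
                             palette = default_palette()) {
  size_class <- match.arg(size_class)
  stopifnot(ncr > 0, ncr < 1, irregularity >= 0, texture >= 0)
  structure(
    list(size_class = size_class, malignant = malignant, ncr = ncr,
         irregularity = irregularity, texture = texture, palette = palette),
    class = "cell_render_spec"
  )
}

#' Draw a cell spec from the benign or malignant morphology distribution
#'
#' Malignant cells have higher mean nucleus-to-cell ratio, contour
#' irregularity and chromatin texture, but the distributions overlap, so
#' downstream classifiers cannot be trivially perfect.
#'
#' @param malignant Logical.
#' @param size_class `"large"`, `"small"`, or `NULL` to pick one at random.
#' @param seed Seed.
#' @param effect Scale on the malignant-vs-benign mean separation
#'   (default 1; larger values render more obviously malignant cells).
#' @export
sample_cell_spec <- function(malignant, size_class = NULL, seed = 1,
                             effect = 1) {
  with_seed(seed, {
    if (is.null(size_class)) {
      size_class <- sample(c("large", "small"), 1)
    }
    if (malignant) {
      ncr <- min(max(stats::rnorm(1, 0.28 + effect * 0.24, 0.10), 0.10), 0.88)
      irr <- abs(stats::rnorm(1, 0.06 + effect * 0.10, 0.06))
      tex <- abs(stats::rnorm(1, 0.05 + effect * 0.09, 0.06))
    } else {
      ncr <- min(max(stats::rnorm(1, 0.28, 0.07), 0.05), 0.85)
      irr <- abs(stats::rnorm(1, 0.06, 0.03))
      tex <- abs(stats::rnorm(1, 0.05, 0.03))
    }
    cell_render_spec(size_class, malignant, ncr, irr, tex)
  })
}

# Smooth periodic boundary perturbation and low-frequency 2-D texture field.
boundary_profile <- function(theta, irregularity, seed_draws) {
  pert <- rep(0, length(theta))
  for (k in 2:5) {
    pert <- pert + seed_draws$amp[k - 1] / k * sin(k * theta + seed_draws$phase[k - 1])
  }
  1 + irregularity * pert
}

texture_field <- function(h, w, draws) {
  xi <- matrix(seq_len(w), h, w, byrow = TRUE)
  yi <- matrix(seq_len(h), h, w)
  f <- sin(xi / draws$p1 + draws$f1) * sin(yi / draws$p2 + draws$f2) +
    0.6 * sin((xi + yi) / draws$p3 + draws$f3)
  f / 1.6
}

#' Render a single synthetic cell
#'
#' Draws a cytoplasm blob with a Fourier-perturbed boundary and an interior
#' nucleus whose area is `ncr` times the cell area, with chromatin texture
#' in the nucleus. The cell always fits its size-class crop (254 or 90 px),
#' and large-class cells have a bounding side above 90 px so size routing is
#' well defined.
#'
#' @param spec A [cell_render_spec()].
#' @param seed Seed; identical spec + seed give bit-identical output.
#' @return A list: `image` (crop array), `mask` (logical matrix covering
#'   exactly the rendered cell pixels), `spec`.
#' @export
render_cell <- function(spec, seed = 1) {
  S <- if (spec$size_class == "large") 254L else 90L
  with_seed(seed, {
    r0 <- if (spec$size_class == "large") stats::runif(1, 58, 105) else stats::runif(1, 18, 38)
    draws <- list(amp = stats::rnorm(4), phase = stats::runif(4, 0, 2 * pi))
    ndraws <- list(amp = stats::rnorm(4), phase = stats::runif(4, 0, 2 * pi))
    tdraws <- list(p1 = stats::runif(1, 2.5, 6), p2 = stats::runif(1, 2.5, 6),
                   p3 = stats::runif(1, 3, 8),
                   f1 = stats::runif(1, 0, 2 * pi), f2 = stats::runif(1, 0, 2 * pi),
                   f3 = stats::runif(1, 0, 2 * pi))
    noff_ang <- stats::runif(1, 0, 2 * pi)
    cyto_jit <- stats::rnorm(1, 0, 0.02)

    cx <- (S + 1) / 2; cy <- (S + 1) / 2
    xi <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
    yi <- matrix(seq_len(S), S, S) - cy
    theta <- atan2(yi, xi)
    d <- sqrt(xi^2 + yi^2)

    rb <- r0 * boundary_profile(theta, spec$irregularity, draws)
    # keep the cell inside the crop with a 2 px margin
    scale_fix <- min(1, (S / 2 - 2) / max(rb))
    rb <- rb * scale_fix
    mask <- d <= rb

    # nucleus: area ratio ncr of the cell, slightly off-centre, own contour
    rn0 <- r0 * scale_fix * sqrt(spec$ncr)
    off <- (r0 * scale_fix - rn0) * 0.35
    nxi <- xi - off * cos(noff_ang)
    nyi <- yi - off * sin(noff_ang)
    ntheta <- atan2(nyi, nxi)
    nd <- sqrt(nxi^2 + nyi^2)
    rnb <- rn0 * boundary_profile(ntheta, spec$irregularity * 0.8, ndraws)
    nucleus <- (nd <= rnb) & mask

    img <- blank_raster(S, S, spec$palette$background)
    tex <- texture_field(S, S, tdraws)
    for (c in 1:3) {
      pane <- img[, , c]
      cyto_col <- spec$palette$cytoplasm[c] * (1 + cyto_jit)
      pane[mask] <- cyto_col * (1 + 0.04 * tex[mask])
      nuc_col <- spec$palette$nucleus[c]
      pane[nucleus] <- nuc_col * (1 + spec$texture * tex[nucleus] * 2)
      img[, , c] <- pmin(pmax(pane, 0), 1)
    }
    list(image = img, mask = mask, spec = spec)
  })
}

#' The six non-single-cell (junk) object categories
#' @export
junk_categories <- function() {
  c("blurry", "incomplete", "fragment", "clump", "impurity", "nucleus_only")
}

#' Render a non-single-cell (junk) object of a given QC category
#'
#' Categories mirror the six reject classes of the quality-control stage:
#' blurry cells, incomplete cells, cell fragments, multicellular clumps,
#' impurities, and bare nuclei.
#'
#' @param category One of [junk_categories()].
#' @param seed Seed.
#' @return A list `image`, `mask`, `category`.
#' @export
render_junk <- function(category = junk_categories(), seed = 1) {
  category <- match.arg(category)
  pal <- default_palette()
  out <- switch(
    category,
    blurry = {
      cell <- render_cell(sample_cell_spec(FALSE, seed = seed * 13 + 1), seed = seed)
      img <- blur_raster(cell$image, sigma = 3)
      list(image = img, mask = cell$mask)
    },
    incomplete = {
      cell <- render_cell(sample_cell_spec(FALSE, seed = seed * 13 + 2), seed = seed)
      cut_at <- with_seed(seed + 5e6, sample(ncol(cell$mask) %/% 2, 1)) +
        ncol(cell$mask) %/% 4
      cell$mask[, cut_at:ncol(cell$mask)] <- FALSE
      # blank the cut-away part of the image too: the object really ends here
      img <- remove_background(cell$image, cell$mask, pal$background)
      list(image = img, mask = cell$mask)
    },
    fragment = with_seed(seed + 1e6, {
      S <- 90L
      r0 <- stats::runif(1, 6, 14)
      blob <- blob_mask(S, r0, irregularity = 0.5)
      img <- blank_raster(S, S, pal$background)
      for (c in 1:3) {
        pane <- img[, , c]
        pane[blob] <- pal$cytoplasm[c] * stats::runif(1, 0.85, 1.1)
        img[, , c] <- pane
      }
      list(image = img, mask = blob)
    }),
    clump = {
      S <- 254L
      img <- blank_raster(S, S, pal$background)
      mask <- matrix(FALSE, S, S)
      n <- with_seed(seed + 2e6, sample(2:4, 1))
      for (k in seq_len(n)) {
        cell <- render_cell(sample_cell_spec(FALSE, size_class = "small",
                                             seed = seed * 17 + k), seed = seed + k)
        off <- with_seed(seed + 3e6 + k,
                         round(stats::runif(2, S * 0.25, S * 0.55)))
        img <- composite_raster(img, cell$image, cell$mask, off[1], off[2])
        sub <- matrix(FALSE, S, S)
        sub <- composite_mask(sub, cell$mask, off[1], off[2])
        mask <- mask | sub
      }
      list(image = img, mask = mask)
    },
    impurity = with_seed(seed + 4e6, {
      S <- 90L
      r0 <- stats::runif(1, 8, 20)
      blob <- blob_mask(S, r0, irregularity = 0.7)
      img <- blank_raster(S, S, pal$background)
      for (c in 1:3) {
        pane <- img[, , c]
        pane[blob] <- pal$impurity[c] * stats::runif(1, 0.8, 1.2)
        img[, , c] <- pane
      }
      list(image = img, mask = blob)
    }),
    nucleus_only = with_seed(seed + 5e6, {
      S <- 90L
      r0 <- stats::runif(1, 8, 18)
      blob <- blob_mask(S, r0, irregularity = 0.15)
      img <- blank_raster(S, S, pal$background)
      for (c in 1:3) {
        pane <- img[, , c]
        pane[blob] <- pal$nucleus[c]
        img[, , c] <- pane
      }
      list(image = img, mask = blob)
    })
  )
  out$category <- category
  out
}

# Irregular blob mask centred in an S x S crop (uses the current RNG stream).
blob_mask <- function(S, r0, irregularity) {
  draws <- list(amp = stats::rnorm(4), phase = stats::runif(4, 0, 2 * pi))
  cx <- (S + 1) / 2
  xi <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
  yi <- matrix(seq_len(S), S, S) - cx
  theta <- atan2(yi, xi)
  rb <- r0 * boundary_profile(theta, irregularity, draws)
  rb <- rb * min(1, (S / 2 - 2) / max(rb))
  sqrt(xi^2 + yi^2) <= rb
}

composite_mask <- function(canvas, mask, x0, y0) {
  ch <- nrow(mask); cw <- ncol(mask)
  H <- nrow(canvas); W <- ncol(canvas)
  ys <- (y0 + 1):(y0 + ch); xs <- (x0 + 1):(x0 + cw)
  keep_y <- ys >= 1 & ys <= H; keep_x <- xs >= 1 & xs <= W
  canvas[ys[keep_y], xs[keep_x]] <-
    canvas[ys[keep_y], xs[keep_x]] | mask[keep_y, keep_x]
  canvas
}

#' Specify a synthetic slide
#'
#' @param n_cells Number of single cells to place.
#' @param etc_fraction True malignant fraction in percent; exactly
#'   `round(n_cells * etc_fraction / 100)` cells are malignant.
#' @param patch_grid `c(rows, cols)` of 1024 x 1024 patches.
#' @param junk_fraction Fraction of *all* placed objects that are
#'   non-single-cell junk.
#' @param effect Malignant morphology effect scale (see
#'   [sample_cell_spec()]).
#' @param seed Seed.
#' @export
slide_spec <- function(n_cells, etc_fraction = 0, patch_grid = c(1, 1),
                       junk_fraction = 0.3, effect = 1, seed = 1) {
  stopifnot(n_cells >= 0, etc_fraction >= 0, etc_fraction <= 100,
            all(patch_grid >= 1), junk_fraction >= 0, junk_fraction < 1,
            effect > 0)
  structure(
    list(n_cells = as.integer(n_cells), etc_fraction = etc_fraction,
         patch_grid = as.integer(patch_grid), junk_fraction = junk_fraction,
         effect = effect, seed = as.integer(seed)),
    class = "slide_spec"
  )
}

#' Render a synthetic whole-slide image with ground truth
#'
#' Places single cells (an exact number of them malignant) and junk objects
#' at non-overlapping positions on a background canvas of
#' `patch_grid * 1024` pixels. Every object gets a ground-truth box in
#' global 0-based half-open pixel coordinates, a run-length-encoded mask,
#' and a label (benign / malignant, or its junk category).
#'
#' @param spec A [slide_spec()].
#' @return A list: `wsi` (RGB array), `annotations` (tibble: object_id, x,
#'   y, w, h, label, size_class, malignant, is_cell, mask_rle), `spec`.
#' @export
render_slide <- function(spec) {
  H <- spec$patch_grid[1] * 1024L
  W <- spec$patch_grid[2] * 1024L
  pal <- default_palette()
  n_mal <- round(spec$n_cells * spec$etc_fraction / 100)
  n_junk <- if (spec$junk_fraction > 0) {
    round(spec$n_cells * spec$junk_fraction / (1 - spec$junk_fraction))
  } else 0L

  with_seed(spec$seed, {
    wsi <- blank_raster(H, W, pal$background)
    noise <- array(stats::rnorm(H * W * 3, 0, 0.008), dim = c(H, W, 3))
    wsi <- pmin(pmax(wsi + noise, 0), 1)

    labels <- c(rep("malignant", n_mal), rep("benign", spec$n_cells - n_mal))
    if (n_junk > 0) {
      labels <- c(labels, sample(junk_categories(), n_junk, replace = TRUE))
    }
    labels <- if (length(labels)) sample(labels) else character(0)

    placed <- list()
    centers <- matrix(numeric(0), ncol = 3) # cx, cy, radius
    for (k in seq_along(labels)) {
      lab <- labels[k]
      obj_seed <- spec$seed * 1000L + k
      if (lab %in% c("benign", "malignant")) {
        cs <- sample_cell_spec(lab == "malignant", seed = obj_seed,
                               effect = if (is.null(spec$effect)) 1 else spec$effect)
        obj <- render_cell(cs, seed = obj_seed)
        obj$label <- lab
        obj$size_class <- cs$size_class
      } else {
        obj <- render_junk(lab, seed = obj_seed)
        obj$label <- lab
        obj$size_class <- NA_character_
      }
      bb <- mask_bbox(obj$mask)
      if (is.null(bb)) next
      rad <- max(bb$w, bb$h) / 2
      ok <- FALSE
      for (try in 1:400) {
        cx <- stats::runif(1, rad + 4, W - rad - 4)
        cy <- stats::runif(1, rad + 4, H - rad - 4)
        # bounding circles may brush (factor 0.95) but objects stay distinct
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                (centers[, 3] + rad) * 0.95)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place ", length(labels), " objects on a ",
             W, "x", H, " slide without overlap")
      }
      centers <- rbind(centers, c(cx, cy, rad))
      # top-left of the crop so that the mask bbox is centred at (cx, cy)
      x0 <- round(cx - bb$x - bb$w / 2)
      y0 <- round(cy - bb$y - bb$h / 2)
      wsi <- composite_raster(wsi, obj$image, obj$mask, x0, y0)
      tight <- obj$mask[bb$y + seq_len(bb$h), bb$x + seq_len(bb$w), drop = FALSE]
      placed[[length(placed) + 1]] <- tibble::tibble(
        object_id = paste0("obj", length(placed) + 1),
        x = x0 + bb$x, y = y0 + bb$y, w = bb$w, h = bb$h,
        label = lab,
        size_class = obj$size_class,
        malignant = identical(lab, "malignant"),
        is_cell = lab %in% c("benign", "malignant"),
        mask_rle = rle_encode(tight)
      )
    }
    annotations <- if (length(placed)) dplyr::bind_rows(placed) else {
      tibble::tibble(object_id = character(0), x = integer(0), y = integer(0),
                     w = integer(0), h = integer(0), label = character(0),
                     size_class = character(0), malignant = logical(0),
                     is_cell = logical(0), mask_rle = character(0))
    }
    list(wsi = wsi, annotations = annotations, spec = spec)
  })
}
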