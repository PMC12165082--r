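# Seven-class quality control: keeps high-quality single cells and rejects
# blurry cells, incomplete cells, cell fragments, multicellular clumps,
# impurities, and bare nuclei.

#' QC category levels
#' @export
qc_categories <- function() {
  c("high_quality", junk_categories())
}

# Morphometric/texture features of a crop, computed on the 224 x 224
# standardized view. `bg_color`/`dist_threshold` come from the detector so
# foreground extraction is consistent across stages.
qc_features <- function(crop, bg_color, dist_threshold) {
  std <- resize_raster(crop, 224L, 224L)
  d <- color_distance(std, bg_color)
  fg <- d > dist_threshold
  area_frac <- mean(fg)
  pal <- default_palette()
  feats <- list(area_frac = area_frac)
  if (!any(fg)) {
    feats <- c(feats, list(
      n_comp = 0, nuc_comp = 0, edge_frac = 0, sharpness = 0, nuc_frac = 0,
      dark_frac = 0, mean_r = 0, mean_g = 0, mean_b = 0,
      fill = 0, long_frac = 0, sd_int = 0
    ))
    return(tibble::as_tibble(feats))
  }
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  n_comp <- sum(sizes >= 30)
  border <- fg
  border[2:(nrow(fg) - 1), 2:(ncol(fg) - 1)] <- FALSE
  edge_frac <- sum(border) / sum(fg)
  nd <- color_distance(std, pal$nucleus)
  cd <- color_distance(std, pal$cytoplasm)
  nuc <- fg & (nd < cd)
  intens <- raster_intensity(std)
  bb <- mask_bbox(fg)
  nlab <- EBImage::bwlabel(nuc)
  nsizes <- tabulate(nlab[nlab > 0])
  tibble::as_tibble(c(feats, list(
    n_comp = n_comp,
    nuc_comp = sum(nsizes >= 25), # multicellular clumps carry several nuclei
    edge_frac = edge_frac,
    sharpness = object_sharpness(crop, bg_color, dist_threshold),
    nuc_frac = sum(nuc) / sum(fg),
    dark_frac = mean(intens[fg] < 0.45),
    mean_r = mean(std[, , 1][fg]),
    mean_g = mean(std[, , 2][fg]),
    mean_b = mean(std[, , 3][fg]),
    fill = sum(fg) / (bb$w * bb$h),
    long_frac = max(bb$w, bb$h) / 224,
    sd_int = stats::sd(intens[fg])
  )))
}

# Sharpness (log Laplacian variance) restricted to the interior of the
# foreground object at native resolution, so background noise does not
# mask blur.
object_sharpness <- function(crop, bg_color, dist_threshold) {
  d <- color_distance(crop, bg_color)
  fg <- d > dist_threshold
  n <- nrow(fg); m <- ncol(fg)
  if (n < 3 || m < 3 || !any(fg)) return(0)
  inner <- fg[2:(n - 1), 2:(m - 1)] &
    fg[1:(n - 2), 2:(m - 1)] & fg[3:n, 2:(m - 1)] &
    fg[2:(n - 1), 1:(m - 2)] & fg[2:(n - 1), 3:m]
  if (sum(inner) < 9) return(0)
  g <- raster_intensity(crop)
  lap <- g[2:(n - 1), 2:(m - 1)] * -4 +
    g[1:(n - 2), 2:(m - 1)] + g[3:n, 2:(m - 1)] +
    g[2:(n - 1), 1:(m - 2)] + g[2:(n - 1), 3:m]
  log1p(stats::var(lap[inner]) * 1e4)
}

#' Train the seven-class QC model
#'
#' A multinomial logistic model on morphometric and texture features of
#' standardized 224 x 224 crops.
#'
#' @param crops List of RGB crop arrays.
#' @param labels Character vector of [qc_categories()] labels, one per crop.
#' @param detector Trained [train_detector()] object (supplies the
#'   background colour model for feature extraction).
#' @param seed Seed (controls the multinomial fit's weight initialisation).
#' @return An `etc_qc_model`.
#' @export
train_qc_model <- function(crops, labels, detector, seed = 1) {
  stopifnot(length(crops) == length(labels),
            all(labels %in% qc_categories()))
  feats <- purrr::map_dfr(crops, qc_features,
                          bg_color = detector$bg_color,
                          dist_threshold = detector$dist_threshold)
  feats$label <- factor(labels, levels = qc_categories())
  fit <- with_seed(seed, {
    utils::capture.output(
      m <- nnet::multinom(label ~ ., data = feats, maxit = 400, MaxNWts = 2000)
    )
    m
  })
  structure(
    list(model = fit, bg_color = detector$bg_color,
         dist_threshold = detector$dist_threshold,
         levels = qc_categories()),
    class = "etc_qc_model"
  )
}

#' Classify a crop into the seven QC categories
#'
#' @param crop RGB crop array.
#' @param qc An `etc_qc_model` from [train_qc_model()].
#' @return A `qc_verdict` list: `category` (argmax) and `probabilities`
#'   (7-vector over [qc_categories()], summing to 1).
#' @export
qc_classify <- function(crop, qc) {
  if (!inherits(qc, "etc_qc_model")) stop("untrained or invalid QC model")
  feats <- qc_features(crop, qc$bg_color, qc$dist_threshold)
  p_raw <- stats::predict(qc$model, newdata = feats, type = "probs")
  probs <- stats::setNames(rep(0, length(qc$levels)), qc$levels)
  if (is.null(dim(p_raw))) {
    probs[names(p_raw)] <- p_raw
  } else {
    probs[colnames(p_raw)] <- p_raw[1, ]
  }
  probs <- probs / sum(probs)
  list(category = names(probs)[which.max(probs)], probabilities = probs)
}
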