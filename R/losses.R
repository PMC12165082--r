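# Training losses of the detection and segmentation stages, as standalone
# numeric functions so their closed forms can be verified directly.

#' Detection loss: squared-IoU + objectness + classification
#'
#' Total loss `lambda_reg * L_IoU + L_obj + L_cls` where
#' `L_IoU = mean over foreground pairs of (1 - IoU^2)`, and the objectness
#' and class terms are binary cross-entropy on logits. With no foreground
#' pairs the IoU term is 0 by convention.
#'
#' @param pred_boxes,true_boxes Tibbles/data frames of matched foreground
#'   boxes (`x`, `y`, `w`, `h`), row i of one matched to row i of the other.
#' @param obj_logits,obj_targets Objectness logits and 0/1 targets (any
#'   length, may be empty).
#' @param cls_logits,cls_targets Classification logits and 0/1 targets.
#' @param lambda_reg Regularization weight for the IoU term (default 0.5).
#' @return A named list: `total`, `iou`, `obj`, `cls`.
#' @export
detection_loss <- function(pred_boxes, true_boxes,
                           obj_logits = numeric(0), obj_targets = numeric(0),
                           cls_logits = numeric(0), cls_targets = numeric(0),
                           lambda_reg = 0.5) {
  n_fg <- if (is.null(pred_boxes)) 0L else nrow(pred_boxes)
  if (n_fg != (if (is.null(true_boxes)) 0L else nrow(true_boxes))) {
    stop("pred_boxes and true_boxes must have the same number of rows")
  }
  l_iou <- if (n_fg == 0) 0 else {
    ious <- vapply(seq_len(n_fg),
                   function(i) iou(pred_boxes[i, ], true_boxes[i, ]),
                   numeric(1))
    mean(1 - ious^2)
  }
  l_obj <- bce_with_logits(obj_logits, obj_targets)
  l_cls <- bce_with_logits(cls_logits, cls_targets)
  list(total = lambda_reg * l_iou + l_obj + l_cls,
       iou = l_iou, obj = l_obj, cls = l_cls)
}

# Numerically stable mean binary cross-entropy on logits
# (log(1 + exp(x)) - t*x form); 0 for empty input.
bce_with_logits <- function(logits, targets) {
  if (length(logits) != length(targets)) stop("logit/target length mismatch")
  if (length(logits) == 0) return(0)
  mean(pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits))))
}

#' Combined Dice + binary cross-entropy segmentation loss
#'
#' `BCE(logits, truth) + (1 - Dice)` where Dice is the soft Dice
#' coefficient `2*sum(p*t) / (sum(p) + sum(t))` of the predicted
#' probabilities `p = sigmoid(logits)` against the 0/1 truth mask.
#'
#' @param logits Numeric matrix/vector of mask logits.
#' @param truth 0/1 (or logical) truth mask of the same shape.
#' @param smooth Additive smoothing of the Dice ratio (default 0: the
#'   closed forms hold exactly).
#' @return A named list: `total`, `bce`, `dice` (the coefficient).
#' @export
dice_bce_loss <- function(logits, truth, smooth = 0) {
  if (length(logits) != length(truth)) stop("shape mismatch")
  truth <- as.numeric(truth)
  p <- stats::plogis(as.numeric(logits))
  dice <- (2 * sum(p * truth) + smooth) / (sum(p) + sum(truth) + smooth)
  bce <- bce_with_logits(as.numeric(logits), truth)
  list(total = bce + (1 - dice), bce = bce, dice = dice)
}
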