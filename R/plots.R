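# ggplot2 views of the main result types.

#' Plot a per-cell copy-number profile
#'
#' Bin-level log2 ratios (points) with segment means (horizontal lines)
#' coloured by state, faceted along chromosomes.
#'
#' @param object A `cna_profile` from [call_states()] or [cna_profile()].
#' @param ratios Optional ratio track; taken from the profile's `ratios`
#'   attribute when present.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cna_profile
#' @export
autoplot.cna_profile <- function(object, ratios = attr(object, "ratios"), ...) {
  segs <- tibble::as_tibble(object)
  segs$chrom <- factor(segs$chrom, unique(segs$chrom))
  p <- ggplot2::ggplot()
  if (!is.null(ratios)) {
    rt <- dplyr::mutate(tibble::as_tibble(ratios),
                        chrom = factor(.data$chrom, levels(segs$chrom)),
                        log2 = log2(pmax(.data$ratio, 1e-3)))
    p <- p + ggplot2::geom_point(
      data = rt,
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$log2),
      size = 0.3, alpha = 0.4, colour = "grey40"
    )
  }
  p +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_log2, yend = .data$mean_log2,
                   colour = .data$state),
      linewidth = 1.1
    ) +
    ggplot2::scale_colour_manual(
      values = c(loss = "#2166AC", neutral = "grey30", gain = "#B2182B")
    ) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "genomic position (bp)", y = "log2 ratio",
                  colour = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(1, "pt"))
}

#' Plot an ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$lo, object$hi)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-slide ETC percentages by truth group
#'
#' @param cohort A tibble with `truth` and `etc_percent` columns.
#' @param cutoff Operating cutoff drawn as a dashed line (default 0.2).
#' @return A ggplot object.
#' @export
plot_etc_percent <- function(cohort, cutoff = 0.2) {
  ggplot2::ggplot(cohort, ggplot2::aes(.data$truth, .data$etc_percent)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2, colour = "red") +
    ggplot2::scale_y_continuous(trans = "sqrt") +
    ggplot2::labs(x = NULL, y = "predicted ETC %") +
    ggplot2::theme_minimal()
}
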