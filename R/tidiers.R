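# broom-style tidy()/glance() methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a channel classifier: discriminant weights
#' @param x An `etc_classifier`.
#' @param ... Unused.
#' @return A tibble of feature terms and their (sign-corrected)
#'   discriminant weights.
#' @method tidy etc_classifier
#' @export
tidy.etc_classifier <- function(x, ...) {
  sc <- x$model$fit$scaling
  tibble::tibble(
    term = rownames(sc),
    estimate = x$model$flip * sc[, 1]
  )
}

#' @rdname tidy.etc_classifier
#' @method glance etc_classifier
#' @export
glance.etc_classifier <- function(x, ...) {
  tibble::tibble(
    channel = x$channel, threshold = x$threshold,
    validation_auc = x$validation$auc, test_auc = x$test$auc,
    test_sensitivity = x$test$sensitivity,
    test_specificity = x$test$specificity
  )
}

#' Tidy a concordance result: per-cell calls
#' @param x A `concordance_result`.
#' @param ... Unused.
#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) {
  x$calls
}

#' @rdname tidy.concordance_result
#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$calls),
    n_eligible = sum(x$calls$eligible),
    n_clusters = length(unique(stats::na.omit(x$calls$cluster))),
    n_malignant = length(x$malignant_ids)
  )
}

#' Tidy a cohort report: the metric table
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) {
  tibble::as_tibble(x$model_metrics)
}

#' @rdname tidy.cohort_report
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tb <- x$table
  tibble::tibble(
    n = sum(tb), tp = tb[["tp"]], fp = tb[["fp"]], fn = tb[["fn"]],
    tn = tb[["tn"]], pct_more_positives = x$pct_more_positives
  )
}
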