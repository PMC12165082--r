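# Slide-level diagnostic model (ETC% + cutoff) and cohort-level statistics.

#' ETC percentage and slide-level call
#'
#' @param n_etc,n_total Predicted ETC count and total (QC-passed) cell
#'   count; `n_total` must be positive.
#' @return `etc_fraction()`: percent. `slide_call()`: `"positive"` when the
#'   percent is at or above the cutoff (boundary positive), else
#'   `"negative"`.
#' @export
etc_fraction <- function(n_etc, n_total) {
  stopifnot(n_total > 0, n_etc >= 0, n_etc <= n_total)
  100 * n_etc / n_total
}

#' @rdname etc_fraction
#' @param etc_percent ETC percentage.
#' @param cutoff Operating cutoff in percent (default 0.2).
#' @export
slide_call <- function(etc_percent, cutoff = 0.2) {
  ifelse(etc_percent >= cutoff, "positive", "negative")
}

#' Round half up to a number of decimals (the convention of printed
#' clinical percentages).
#' @param x Numeric. @param digits Decimals (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Diagnostic metrics with confidence intervals from a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV
#' tn/(tn+fn), each in percent with an exact Clopper-Pearson 95% CI
#' (configurable to Wald). Metrics with a zero margin are reported as `NA`.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @param ci `"clopper-pearson"` (default) or `"wald"`.
#' @return A `diag_metrics` tibble: metric, numerator, denominator,
#'   estimate (percent), lo, hi.
#' @export
confusion_metrics <- function(tp, fp, fn, tn, conf_level = 0.95,
                              ci = c("clopper-pearson", "wald")) {
  ci <- match.arg(ci)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  one <- function(name, num, den) {
    if (den == 0) {
      return(tibble::tibble(metric = name, numerator = num, denominator = den,
                            estimate = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    p <- num / den
    if (ci == "clopper-pearson") {
      bt <- stats::binom.test(num, den, conf.level = conf_level)
      lo <- bt$conf.int[1]; hi <- bt$conf.int[2]
    } else {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      se <- sqrt(p * (1 - p) / den)
      lo <- max(0, p - z * se); hi <- min(1, p + z * se)
    }
    tibble::tibble(metric = name, numerator = num, denominator = den,
                   estimate = 100 * p, lo = 100 * lo, hi = 100 * hi)
  }
  out <- dplyr::bind_rows(
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("ppv", tp, tp + fp),
    one("npv", tn, tn + fn)
  )
  class(out) <- c("diag_metrics", class(out))
  attr(out, "table") <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  out
}

#' Find the operating cutoff on ETC percentages
#'
#' Candidates are midpoints between consecutive sorted unique values (plus
#' one below the minimum and one above the maximum); a slide is positive at
#' value >= cutoff. The default rule maximizes sensitivity subject to
#' maximal specificity; `rule = "youden"` maximizes sensitivity +
#' specificity - 1.
#'
#' @param values Numeric per-slide ETC percentages.
#' @param truth Logical (or 0/1): TRUE = cancer.
#' @param rule `"spec_first"` (default) or `"youden"`.
#' @return The cutoff, with attributes `sensitivity`, `specificity`,
#'   `rule`.
#' @export
find_cutoff <- function(values, truth, rule = c("spec_first", "youden")) {
  rule <- match.arg(rule)
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2) stop("both classes must be present")
  u <- sort(unique(values))
  if (length(u) == 1) warning("all values identical; cutoff is degenerate")
  cands <- if (length(u) == 1) u else {
    c(u[1] - 1e-9, u[-length(u)] + diff(u) / 2, u[length(u)] + 1e-9)
  }
  sens <- vapply(cands, function(t) mean(values[truth] >= t), numeric(1))
  spec <- vapply(cands, function(t) mean(values[!truth] < t), numeric(1))
  pick <- if (rule == "spec_first") {
    best_spec <- max(spec)
    which(spec == best_spec)[which.max(sens[spec == best_spec])]
  } else {
    which.max(sens + spec - 1)
  }
  out <- cands[pick]
  attr(out, "sensitivity") <- sens[pick]
  attr(out, "specificity") <- spec[pick]
  attr(out, "rule") <- rule
  out
}

#' Sensitivity-corrected tumor-cell proportion
#'
#' Divides an observed proportion by the detection sensitivity of the
#' model that produced it, capping at 100% with a warning.
#'
#' @param observed Observed proportion in percent.
#' @param sensitivity Detection sensitivity in percent (> 0).
#' @return Corrected proportion in percent.
#' @export
corrected_proportion <- function(observed, sensitivity) {
  if (sensitivity <= 0) stop("sensitivity must be positive")
  out <- 100 * observed / sensitivity
  if (out > 100) {
    warning("corrected proportion exceeds 100%; capped")
    out <- 100
  }
  out
}

#' ROC AUC with a Wald confidence interval
#'
#' The AUC is the normalized rank-sum statistic (identical to the
#' trapezoidal area under the empirical ROC curve, ties counted half);
#' the CI uses the Hanley-McNeil variance estimate.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) truth.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `auc`, `lo`, `hi`, `n_pos`, `n_neg`, and `roc` (tibble
#'   of fpr/tpr points).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
    (n1 * n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(max(v, 0))
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(c(Inf, thr, -Inf), function(t) {
    tibble::tibble(threshold = t,
                   fpr = mean(scores[!labels] >= t),
                   tpr = mean(scores[labels] >= t))
  })
  structure(
    list(auc = auc, lo = max(0, auc - half), hi = min(1, auc + half),
         n_pos = n1, n_neg = n0, roc = pts),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, x$lo, x$hi, x$n_pos, x$n_neg))
  invisible(x)
}

#' Two-group comparisons used in cohort reporting
#'
#' Thin delegation to the standard tests: Mann-Whitney (unpaired Wilcoxon),
#' paired Wilcoxon signed-rank, or Pearson's chi-square (no continuity
#' correction).
#'
#' @param x,y Numeric vectors, or for `kind = "chi-square"` a 2x2 matrix in
#'   `x` (`y` ignored).
#' @param kind One of `"mann-whitney"`, `"wilcoxon-paired"`,
#'   `"chi-square"`.
#' @return A tibble: kind, statistic, p_value, n.
#' @export
compare_groups <- function(x, y = NULL,
                           kind = c("mann-whitney", "wilcoxon-paired",
                                    "chi-square")) {
  kind <- match.arg(kind)
  res <- switch(
    kind,
    "mann-whitney" = {
      if (length(x) < 2 || length(y) < 2) warning("very small groups")
      t <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      list(stat = unname(t$statistic), p = t$p.value, n = length(x) + length(y))
    },
    "wilcoxon-paired" = {
      stopifnot(length(x) == length(y))
      if (all(x == y)) {
        list(stat = 0, p = 1, n = length(x)) # no signed ranks: no evidence
      } else {
        t <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                 exact = FALSE))
        list(stat = unname(t$statistic), p = t$p.value, n = length(x))
      }
    },
    "chi-square" = {
      stopifnot(is.matrix(x), all(dim(x) == c(2, 2)))
      t <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
      list(stat = unname(t$statistic), p = t$p.value, n = sum(x))
    }
  )
  tibble::tibble(kind = kind, statistic = res$stat, p_value = res$p, n = res$n)
}

#' Cohort-level diagnostic report
#'
#' Confusion tables and metrics for the model (and optionally conventional
#' cytology) against the truth labels, the percent increase in positive
#' findings over cytology among cancer patients, and stratified
#' sensitivities when a `stratum` column is present.
#'
#' @param slides A tibble with `patient_id`, `etc_percent` (or a logical
#'   `call`), and optionally `cytology_result` (`"positive"`/`"negative"`).
#' @param truth A tibble with `patient_id` and `truth`
#'   (`"cancer"`/`"control"`), optionally `stratum`.
#' @param cutoff Operating cutoff applied to `etc_percent` when `call` is
#'   absent (default 0.2).
#' @return A `cohort_report` list: `model_metrics`, `cytology_metrics`
#'   (NULL without cytology), `pct_more_positives`, `strata`, `table`.
#' @export
cohort_report <- function(slides, truth, cutoff = 0.2) {
  stopifnot("patient_id" %in% names(slides), "patient_id" %in% names(truth))
  df <- dplyr::inner_join(slides, truth, by = "patient_id")
  if (nrow(df) != nrow(slides) || nrow(df) != nrow(truth)) {
    stop("patient ids of slides and truth tables do not match")
  }
  if (!"call" %in% names(df)) {
    df$call <- slide_call(df$etc_percent, cutoff) == "positive"
  }
  df$cancer <- df$truth == "cancer"
  tab <- c(
    tp = sum(df$call & df$cancer), fp = sum(df$call & !df$cancer),
    fn = sum(!df$call & df$cancer), tn = sum(!df$call & !df$cancer)
  )
  model_metrics <- confusion_metrics(tab["tp"], tab["fp"], tab["fn"], tab["tn"])
  cyto_metrics <- NULL
  pct_more <- NA_real_
  if ("cytology_result" %in% names(df)) {
    cy <- df$cytology_result == "positive"
    cyto_metrics <- confusion_metrics(
      sum(cy & df$cancer), sum(cy & !df$cancer),
      sum(!cy & df$cancer), sum(!cy & !df$cancer)
    )
    n_cy <- sum(cy & df$cancer)
    n_mod <- sum(df$call & df$cancer)
    pct_more <- if (n_cy > 0) 100 * (n_mod - n_cy) / n_cy else NA_real_
  }
  strata <- NULL
  if ("stratum" %in% names(df)) {
    strata <- df |>
      dplyr::filter(.data$cancer) |>
      dplyr::group_by(.data$stratum) |>
      dplyr::summarise(
        n = dplyr::n(), detected = sum(.data$call),
        sensitivity = 100 * mean(.data$call), .groups = "drop"
      )
  }
  structure(
    list(model_metrics = model_metrics, cytology_metrics = cyto_metrics,
         pct_more_positives = pct_more, strata = strata, table = tab,
         data = df),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort diagnostic report (", sum(x$table), " patients)\n", sep = "")
  m <- x$model_metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-11s %5.1f%%  (%d/%d, 95%% CI %.1f-%.1f)\n",
                m$metric[i], round_half_up(m$estimate[i]),
                m$numerator[i], m$denominator[i], m$lo[i], m$hi[i]))
  }
  if (!is.na(x$pct_more_positives)) {
    cat(sprintf("  %.0f%% more positive findings than cytology\n",
                x$pct_more_positives))
  }
  invisible(x)
}
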