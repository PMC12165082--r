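test_that("ETC fraction and the slide call treat the boundary as positive", {
  expect_equal(etc_fraction(40, 20000), 0.2)
  expect_equal(slide_call(etc_fraction(40, 20000)), "positive")
  expect_equal(slide_call(etc_fraction(39, 20000)), "negative")
  expect_equal(slide_call(etc_fraction(0, 500)), "negative")
  expect_error(etc_fraction(1, 0))
  # monotone in the ETC count for fixed total
  calls <- slide_call(vapply(0:80, etc_fraction, numeric(1),
                             n_total = 20000))
  expect_true(all(diff(calls == "positive") >= 0))
})

test_that("confusion metrics reproduce printed one-decimal percentages", {
  m <- confusion_metrics(tp = 47, fp = 1, fn = 31, tn = 34)
  est <- setNames(round_half_up(m$estimate), m$metric)
  expect_equal(unname(est["sensitivity"]), 60.3)
  expect_equal(unname(est["specificity"]), 97.1)

  # degenerate margins are reported as undefined, not errors
  d <- confusion_metrics(0, 0, 0, 10)
  expect_true(is.na(d$estimate[d$metric == "sensitivity"]))
  expect_true(is.na(d$estimate[d$metric == "ppv"]))
  expect_equal(d$estimate[d$metric == "specificity"], 100)

  # Clopper-Pearson interval contains the point estimate
  m2 <- confusion_metrics(8, 2, 3, 12)
  expect_true(all(m2$lo <= m2$estimate & m2$estimate <= m2$hi))
  w <- confusion_metrics(8, 2, 3, 12, ci = "wald")
  expect_true(all(w$lo <= w$estimate & w$estimate <= w$hi))
})

test_that("PPV from sensitivity/specificity/prevalence equals the table PPV", {
  tab <- c(tp = 33, fp = 4, fn = 11, tn = 52)
  m <- confusion_metrics(tab["tp"], tab["fp"], tab["fn"], tab["tn"])
  sens <- m$estimate[m$metric == "sensitivity"] / 100
  spec <- m$estimate[m$metric == "specificity"] / 100
  prev <- (tab["tp"] + tab["fn"]) / sum(tab)
  bayes_ppv <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
  expect_equal(unname(bayes_ppv * 100),
               unname(m$estimate[m$metric == "ppv"]))
})

test_that("cutoff discovery matches the exhaustive sweep oracle", {
  # perfectly separated: midpoint of the gap
  fc <- find_cutoff(c(0.05, 0.1, 0.5, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.numeric(fc), 0.3)
  expect_equal(attr(fc, "sensitivity"), 1)
  expect_equal(attr(fc, "specificity"), 1)

  set.seed(17)
  vals <- c(rlnorm(60, log(0.4), 1), rlnorm(40, log(0.07), 0.8))
  truth <- rep(c(TRUE, FALSE), c(60, 40))
  got <- as.numeric(find_cutoff(vals, truth))
  u <- sort(unique(vals))
  cands <- c(u[1] - 1e-9, u[-length(u)] + diff(u) / 2, u[length(u)] + 1e-9)
  sens <- vapply(cands, function(t) mean(vals[truth] >= t), numeric(1))
  spec <- vapply(cands, function(t) mean(vals[!truth] < t), numeric(1))
  best <- max(spec)
  oracle <- cands[spec == best][which.max(sens[spec == best])]
  expect_equal(got, oracle)
  # the default rule reproduces maximal specificity on its own data
  expect_equal(attr(find_cutoff(vals, truth), "specificity"), best)

  youden <- as.numeric(find_cutoff(vals, truth, rule = "youden"))
  expect_equal(youden, cands[which.max(sens + spec - 1)])

  expect_warning(find_cutoff(c(1, 1), c(TRUE, FALSE)), "degenerate")
  expect_error(find_cutoff(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("sensitivity correction divides and caps at 100", {
  expect_equal(round_half_up(corrected_proportion(54.8, 79.0)), 69.4)
  expect_equal(corrected_proportion(37, 100), 37)
  expect_warning(capped <- corrected_proportion(90, 80), "capped")
  expect_equal(capped, 100)
  expect_error(corrected_proportion(10, 0))
})

test_that("AUC equals the all-pairs rank statistic and handles the limits", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))$auc, 1)

  set.seed(23)
  s <- rnorm(2000); l <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.05)

  s10 <- c(0.1, 0.8, 0.35, 0.7, 0.7, 0.2, 0.9, 0.4, 0.6, 0.5)
  l10 <- c(0, 1, 0, 1, 0, 0, 1, 1, 0, 1)
  pairs <- expand.grid(p = s10[l10 == 1], n = s10[l10 == 0])
  oracle <- mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
  r <- roc_auc(s10, l10)
  expect_equal(r$auc, oracle, tolerance = 1e-12)
  expect_true(r$lo <= r$auc && r$auc <= r$hi)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("group comparisons delegate to the standard two-sided tests", {
  # identical paired vectors: p = 1 by convention
  expect_equal(compare_groups(1:5, 1:5, kind = "wilcoxon-paired")$p_value, 1)

  cs <- compare_groups(matrix(c(50, 0, 0, 50), 2, 2), kind = "chi-square")
  expect_lt(cs$p_value, 0.001)

  x <- c(1.2, 3.4, 0.5); y <- c(2.2, 5.1, 4.4, 3.3)
  u <- compare_groups(x, y, kind = "mann-whitney")$statistic
  enum <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(u), enum)
})

test_that("cohort report reproduces printed discovery-cohort metrics", {
  # 89 cancer (40 detected: all 13 cytology-positive + 27 of 76
  # cytology-negative), 39 controls all negative
  slides <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:128),
    call = rep(c(TRUE, FALSE, FALSE), c(40, 49, 39)),
    cytology_result = rep(c("positive", "negative", "negative", "negative"),
                          c(13, 27, 49, 39))
  )
  truth <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:128),
    truth = rep(c("cancer", "control"), c(89, 39))
  )
  rep_ <- cohort_report(slides, truth)
  est <- setNames(round_half_up(rep_$model_metrics$estimate),
                  rep_$model_metrics$metric)
  expect_equal(unname(est), c(44.9, 100.0, 100.0, 44.3))
  expect_equal(rep_$pct_more_positives, 100 * (40 - 13) / 13)

  # identical model and cytology calls: 0% increase
  same <- dplyr::mutate(slides,
                        cytology_result = ifelse(call, "positive", "negative"))
  expect_equal(cohort_report(same, truth)$pct_more_positives, 0)

  expect_error(
    cohort_report(slides[1:100, ], truth),
    "do not match"
  )
})

test_that("cohort report equals a hand recount on synthetic calls", {
  set.seed(29)
  n <- 60
  truth <- tibble::tibble(
    patient_id = sprintf("S%02d", 1:n),
    truth = sample(c("cancer", "control"), n, replace = TRUE),
    stratum = sample(c("early", "advanced"), n, replace = TRUE)
  )
  slides <- tibble::tibble(
    patient_id = truth$patient_id,
    etc_percent = ifelse(truth$truth == "cancer",
                         rlnorm(n, log(0.5), 1), rlnorm(n, log(0.05), 1))
  )
  rep_ <- cohort_report(slides, truth, cutoff = 0.2)
  call <- slides$etc_percent >= 0.2
  cancer <- truth$truth == "cancer"
  expect_equal(unname(rep_$table),
               c(sum(call & cancer), sum(call & !cancer),
                 sum(!call & cancer), sum(!call & !cancer)))
  g <- glance(rep_)
  expect_equal(g$n, n)
  strat <- rep_$strata
  for (s in strat$stratum) {
    expect_equal(strat$sensitivity[strat$stratum == s],
                 100 * mean(call[cancer & truth$stratum == s]))
  }
})
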