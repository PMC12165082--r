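# Trained-model behaviour. Models come from the shared fixture (one
# seeded training run reused across files).

test_that("the detector recovers cells on held-out patches and is deterministic", {
  models <- fixture_models()
  expect_gte(models$detector$validation$recall, 0.85)
  expect_gte(models$detector$validation$precision, 0.7)

  # retraining with the same seed reproduces the validation metrics exactly
  patches <- dplyr::bind_rows(lapply(1:6, function(i) {
    sl <- render_slide(slide_spec(n_cells = 12, etc_fraction = 25,
                                  junk_fraction = 0.2, seed = 400 + i))
    tibble::tibble(pixels = list(sl$wsi),
                   boxes = list(sl$annotations[, c("x", "y", "w", "h")]))
  }))
  d1 <- train_detector(patches, seed = 5)
  d2 <- train_detector(patches, seed = 5)
  expect_identical(d1$validation, d2$validation)
  expect_identical(coef(d1$model), coef(d2$model))
})

test_that("a background-only patch yields no detections", {
  models <- fixture_models()
  bg <- etcscreen:::blank_raster(512, 512, default_palette()$background)
  expect_equal(nrow(detect_cells(bg, models$detector)), 0)
})

test_that("QC verdicts are calibrated probabilities with accurate categories", {
  models <- fixture_models()
  # held-out crops (seeds disjoint from the training generator)
  n_per <- 6
  crops <- list(); labels <- character(0); k <- 0
  for (cat in qc_categories()) {
    for (i in seq_len(n_per)) {
      k <- k + 1
      obj <- if (cat == "high_quality") {
        render_cell(sample_cell_spec(i %% 2 == 0, seed = 7e6 + k),
                    seed = 8e6 + k)
      } else {
        render_junk(cat, seed = 8e6 + k)
      }
      crops[[k]] <- obj$image
      labels[k] <- cat
    }
  }
  verdicts <- lapply(crops, qc_classify, qc = models$qc)
  for (v in verdicts) {
    expect_equal(sum(v$probabilities), 1, tolerance = 1e-6)
    expect_true(all(v$probabilities >= 0))
    expect_equal(v$category,
                 names(v$probabilities)[which.max(v$probabilities)])
  }
  pred <- vapply(verdicts, `[[`, character(1), "category")
  expect_gte(mean(pred == labels), 0.8)
  # the pass/reject split itself is cleaner than the 7-way assignment
  expect_gte(mean((pred == "high_quality") == (labels == "high_quality")), 0.9)
  expect_error(qc_classify(crops[[1]], list()), "untrained")
})

test_that("the segmenter reaches held-out Dice >= 0.85 and flags empty crops", {
  models <- fixture_models()
  crops <- list(); masks <- list()
  for (i in 1:20) {
    cell <- render_cell(sample_cell_spec(i %% 2 == 0, seed = 9e6 + i),
                        seed = 9.5e6 + i)
    crops[[i]] <- cell$image
    masks[[i]] <- cell$mask
  }
  expect_gte(segmenter_dice(models$segmenter, crops, masks), 0.85)

  bg <- etcscreen:::blank_raster(90, 90, default_palette()$background)
  seg <- segment_cell(bg, models$segmenter)
  expect_true(seg$empty)
  expect_false(any(seg$mask))
})

test_that("threshold calibration picks the smallest qualifying cutoff", {
  # separable scores: smallest candidate with full specificity is the
  # midpoint of the gap
  thr <- calibrate_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
                             spec_min = 0.998)
  expect_equal(as.numeric(thr), 0.5)
  expect_equal(attr(thr, "specificity"), 1)

  expect_warning(
    thr2 <- calibrate_threshold(c(0.9, 0.1), c(0, 1), spec_min = 0.998),
    "unattainable"
  )
  expect_gt(as.numeric(thr2), 0.9)
  expect_error(calibrate_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("threshold calibration equals an exhaustive sweep oracle", {
  set.seed(31)
  scores <- round(c(rbeta(500, 2, 5), rbeta(500, 5, 2)), 3)
  labels <- rep(c(FALSE, TRUE), each = 500)
  for (spec_min in c(0.9, 0.998)) {
    got <- as.numeric(calibrate_threshold(scores, labels, spec_min))
    u <- sort(unique(scores))
    cands <- sort(unique(c(u, u[-length(u)] + diff(u) / 2, max(u) + 1e-6)))
    neg <- scores[!labels]
    ok <- cands[vapply(cands, function(t) mean(neg < t) >= spec_min,
                       logical(1))]
    expect_equal(got, min(ok))
  }
})

test_that("channel classifiers hold calibrated specificity by construction", {
  models <- fixture_models()
  for (ch in c("large", "small")) {
    expect_gte(models[[ch]]$validation$specificity, 0.998)
    expect_gte(models[[ch]]$test$auc, 0.9)
  }
})
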