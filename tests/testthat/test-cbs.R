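ratio_track <- function(ratios, chrom = "1") {
  n <- length(ratios)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * 5e5,
                 end = seq_len(n) * 5e5, ratio = ratios)
}

test_that("a flat noiseless track yields one segment per chromosome", {
  rt <- dplyr::bind_rows(ratio_track(rep(1, 60), "1"),
                         ratio_track(rep(1, 40), "2"))
  segs <- segment_cbs(rt)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_bins, c(60L, 40L))
})

test_that("a noiseless half-chromosome step breaks exactly at the step", {
  rt <- ratio_track(c(rep(1, 50), rep(1.5, 50)))
  segs <- segment_cbs(rt)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end_bin[1], 50L)
  expect_equal(segs$mean_log2, c(0, log2(1.5)), tolerance = 1e-12)
})

test_that("identical chromosomes segment identically", {
  set.seed(21)
  base <- c(rep(1, 40), rep(1.45, 30), rep(1, 50)) *
    exp(rnorm(120, 0, 0.15))
  rt <- dplyr::bind_rows(ratio_track(base, "1"), ratio_track(base, "2"))
  segs <- segment_cbs(rt)
  s1 <- segs[segs$chrom == "1", c("start_bin", "end_bin", "mean_log2")]
  s2 <- segs[segs$chrom == "2", c("start_bin", "end_bin", "mean_log2")]
  expect_equal(s1, s2)
})

test_that("state calling matches a brute-force threshold sweep", {
  set.seed(5)
  means <- runif(40, -1, 1)
  segs <- tibble::tibble(
    chrom = "1", start_bin = seq(1, by = 10, length.out = 40),
    end_bin = seq(10, by = 10, length.out = 40),
    start = (0:39) * 5e6, end = (1:40) * 5e6,
    n_bins = rep(10L, 40), mean_log2 = means
  )
  for (thr in c(0.1, 0.25, 0.4)) {
    got <- call_states(segs, gain = thr, loss = -thr, center = FALSE)$state
    oracle <- ifelse(means >= thr, "gain", ifelse(means <= -thr, "loss",
                                                  "neutral"))
    expect_identical(got, oracle)
  }
})

test_that("profiles are centred on the largest-mass mode before calling", {
  # whole track shifted by +0.3: the dominant (neutral) mass defines zero
  segs <- tibble::tibble(
    chrom = "1", start_bin = c(1, 81), end_bin = c(80, 100),
    start = c(0, 8e7), end = c(8e7, 1e8),
    n_bins = c(80L, 20L), mean_log2 = c(0.3, 0.885)
  )
  prof <- call_states(segs)
  expect_equal(attr(prof, "baseline"), 0.3)
  expect_identical(prof$state, c("neutral", "gain"))
})

test_that("CNA burden is the altered fraction of the autosomal genome", {
  # two 100 Mb autosomes, one 50 Mb gain -> 25%
  segs <- tibble::tibble(
    chrom = c("1", "1", "2"), start_bin = c(1, 101, 1),
    end_bin = c(100, 200, 200),
    start = c(0, 5e7, 0), end = c(5e7, 1e8, 1e8),
    n_bins = c(100L, 100L, 200L), mean_log2 = c(0.58, 0, 0)
  )
  prof <- call_states(segs, center = FALSE)
  expect_equal(cna_burden(prof), 25)

  flat <- call_states(dplyr::mutate(segs, mean_log2 = 0), center = FALSE)
  expect_equal(cna_burden(flat), 0)

  all_alt <- call_states(dplyr::mutate(segs, mean_log2 = 0.58), center = FALSE)
  expect_equal(cna_burden(all_alt), 100)

  # sex chromosomes are excluded from the denominator
  with_x <- dplyr::bind_rows(
    segs, tibble::tibble(chrom = "X", start_bin = 1, end_bin = 200,
                         start = 0, end = 1e8, n_bins = 200L,
                         mean_log2 = 0.58))
  expect_equal(cna_burden(call_states(with_x, center = FALSE)), 25)
})

test_that("the full profiling pipeline recovers a planted clone", {
  bins <- fixture_genome()
  clone <- clone_spec(data.frame(chrom = c("1", "3"), start_bin = c(1, 41),
                                 end_bin = c(120, 100), state = c(3, 1)))
  cc <- simulate_cell_counts(clone, bins,
                             noise_spec(200, target_mapd = 0.3, seed = 77))
  prof <- cna_profile(cc)
  expect_true(attr(prof, "qc_pass"))
  expect_lt(abs(attr(prof, "mapd") - 0.3), 0.07)
  planted <- 100 * (120 + 60) / nrow(bins)
  expect_lt(abs(attr(prof, "burden") - planted), 3)
  expect_identical(
    unique(prof$state[prof$chrom == "1"]), "gain")
})
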