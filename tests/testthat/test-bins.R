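test_that("make_bins applies the equal-width + merged-remainder rule", {
  b <- make_bins(c("1" = 1e6), 5e5)
  expect_equal(nrow(b), 2)
  expect_equal(b$start, c(0, 5e5))
  expect_equal(b$end, c(5e5, 1e6))

  # remainder under half a width merges into the last bin
  b <- make_bins(c("1" = 1.2e6), 5e5)
  expect_equal(nrow(b), 2)
  expect_equal(b$end[2] - b$start[2], 7e5)

  # remainder of at least half a width becomes its own bin
  b <- make_bins(c("1" = 1.8e6), 5e5)
  expect_equal(nrow(b), 4)
  expect_equal(b$end[4] - b$start[4], 3e5)

  # width above the chromosome length: one bin covering it
  b <- make_bins(c("1" = 3e5), 5e5)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(0, 3e5))

  expect_error(make_bins(c("1" = 1e6), 0))
  expect_false(any(make_bins(c("X" = 1e6), 5e5)$autosome))
})

test_that("count_in_bins uses half-open membership and conserves reads", {
  bins <- make_bins(c("1" = 1e6), 5e5)
  pos <- tibble::tibble(chrom = "1", pos = c(0, 499999, 500000, 999999))
  cb <- count_in_bins(pos, bins)
  expect_equal(cb$count, c(2L, 2L))

  pos10 <- tibble::tibble(chrom = "1", pos = seq(0, 9e5, length.out = 10))
  expect_equal(sum(count_in_bins(pos10, bins)$count), 10)

  # unknown chromosome is skipped and logged
  skipped <- count_in_bins(tibble::tibble(chrom = c("1", "7"), pos = c(1, 1)),
                           bins)
  expect_equal(attr(skipped, "n_skipped"), 1L)
})

test_that("count_in_bins agrees with a brute-force interval scan", {
  set.seed(4)
  bins <- make_bins(tibble::tibble(chrom = c("1", "2"), length = c(3e6, 2e6)),
                    5e5)
  pos <- tibble::tibble(
    chrom = sample(c("1", "2"), 300, replace = TRUE),
    pos = round(runif(300, 0, 1.9e6))
  )
  fast <- count_in_bins(pos, bins)$count
  slow <- vapply(seq_len(nrow(bins)), function(i) {
    sum(pos$chrom == bins$chrom[i] & pos$pos >= bins$start[i] &
          pos$pos < bins$end[i])
  }, numeric(1))
  expect_identical(fast, as.integer(slow))
})

test_that("gc_normalize flattens a pure quadratic GC trend and preserves the mean", {
  bins <- simulate_bin_gc(make_bins(c("1" = 5e7)), seed = 3)
  mu <- 200 * etcscreen:::gc_bias_curve(bins$gc, c(1.0, -6.0))
  counts <- dplyr::mutate(bins, cell_id = "c", count = as.integer(round(mu)))
  corrected <- gc_normalize(counts)$corrected
  expect_lt(max(abs(corrected / mean(corrected) - 1)), 0.02)
  expect_lt(abs(mean(corrected) - mean(counts$count)) / mean(counts$count),
            1e-6)

  # GC-independent counts: correction is the identity within 1%
  flat <- dplyr::mutate(bins, cell_id = "c", count = 200L)
  expect_lt(max(abs(gc_normalize(flat)$corrected - 200) / 200), 0.01)

  expect_error(gc_normalize(dplyr::mutate(bins, cell_id = "c", count = 0L)),
               "zero")
})

test_that("to_ratios normalizes to mean 1", {
  rt <- to_ratios(tibble::tibble(chrom = "1", start = 0:2, end = 1:3,
                                 count = c(10L, 20L, 30L)))
  expect_equal(rt$ratio, c(0.5, 1.0, 1.5))
  set.seed(8)
  rt2 <- to_ratios(tibble::tibble(chrom = "1", start = 1:50, end = 2:51,
                                  count = rpois(50, 80)))
  expect_equal(mean(rt2$ratio), 1)
  expect_error(to_ratios(tibble::tibble(chrom = "1", count = c(0L, 0L))))
})

test_that("mapd matches hand computation and gates QC at 0.45", {
  m <- mapd(c(1.0, 1.2, 0.8))
  expect_equal(as.numeric(m), 0.3)
  expect_true(attr(m, "qc_pass"))

  expect_equal(as.numeric(mapd(rep(1, 10))), 0)

  # a cell measured just above the threshold fails QC
  x <- c(1, 1.46, 1)  # mapd = 0.46
  expect_false(attr(mapd(x), "qc_pass"))
  expect_true(attr(mapd(c(1, 1.45, 1) - 0.0), "qc_pass")) # 0.45 passes

  # adjacent pairs are within-chromosome only; constant shift leaves it alone
  rt <- tibble::tibble(chrom = rep(c("1", "2"), each = 3),
                       ratio = c(1, 1.2, 0.8, 1, 1.2, 0.8))
  expect_equal(as.numeric(mapd(rt)), 0.3)
  rt$ratio <- rt$ratio + 5
  expect_equal(as.numeric(mapd(rt)), 0.3)

  expect_error(mapd(1.0), "2 bins")
})
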