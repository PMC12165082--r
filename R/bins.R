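#' Build fixed-width genomic bins
#'
#' Partitions each chromosome into bins of (approximately) `target_width`
#' base pairs. Each chromosome gets `floor(length / width)` equal-width bins;
#' a final remainder shorter than half the target width is merged into the
#' last bin, otherwise it becomes its own bin. Coordinates are 0-based,
#' half-open.
#'
#' @param chrom_lengths A data frame with columns `chrom` and `length` (bp),
#'   or a named numeric vector of chromosome lengths. Chromosome names "X"
#'   and "Y" (with or without a "chr" prefix) are flagged as sex chromosomes.
#' @param target_width Target bin width in bp (default 500 kb).
#' @param gc Optional numeric vector of per-bin GC fractions, recycled not at
#'   all: must match the number of bins produced (use [simulate_bin_gc()] to
#'   attach a synthetic GC landscape).
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `gc`, `autosome`.
#' @export
make_bins <- function(chrom_lengths, target_width = 5e5, gc = NULL) {
  if (target_width <= 0) stop("`target_width` must be positive")
  if (is.numeric(chrom_lengths) && !is.null(names(chrom_lengths))) {
    chrom_lengths <- tibble::tibble(
      chrom = names(chrom_lengths),
      length = unname(chrom_lengths)
    )
  }
  stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
  if (any(chrom_lengths$length <= 0)) stop("chromosome lengths must be positive")

  one_chrom <- function(chrom, len) {
    n <- floor(len / target_width)
    if (n == 0L) {
      starts <- 0
      ends <- len
    } else {
      starts <- (seq_len(n) - 1) * target_width
      ends <- seq_len(n) * target_width
      rem <- len - n * target_width
      if (rem > 0 && rem < target_width / 2) {
        ends[n] <- len            # merge short remainder into last bin
      } else if (rem > 0) {
        starts <- c(starts, n * target_width)
        ends <- c(ends, len)
      }
    }
    tibble::tibble(chrom = chrom, start = starts, end = ends)
  }

  bins <- purrr::map2_dfr(chrom_lengths$chrom, chrom_lengths$length, one_chrom)
  bins$autosome <- !grepl("^(chr)?[XY]$", bins$chrom, ignore.case = TRUE)
  bins$gc <- if (is.null(gc)) NA_real_ else {
    stopifnot(length(gc) == nrow(bins))
    gc
  }
  bins[, c("chrom", "start", "end", "gc", "autosome")]
}

#' Count aligned read positions in genomic bins
#'
#' Each position increments exactly one bin under the half-open convention
#' (`start <= pos < end`). Positions on chromosomes absent from `bins` are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param positions Data frame with columns `chrom` and `pos` (0-based bp).
#' @param bins Bins from [make_bins()].
#' @param cell_id Identifier attached to the output (default "cell").
#'
#' @return A tibble `bin_counts`: columns of `bins` plus `cell_id` and
#'   `count`; attribute `n_skipped` holds the number of off-reference reads.
#' @export
count_in_bins <- function(positions, bins, cell_id = "cell") {
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  counts <- integer(nrow(bins))
  skipped <- 0L
  for (ch in unique(positions$chrom)) {
    idx <- which(bins$chrom == ch)
    pos <- positions$pos[positions$chrom == ch]
    if (length(idx) == 0L) {
      skipped <- skipped + length(pos)
      next
    }
    # half-open membership: bin i gets start[i] <= pos < end[i]
    brk <- c(bins$start[idx], bins$end[idx][length(idx)])
    inside <- pos >= brk[1] & pos < brk[length(brk)]
    skipped <- skipped + sum(!inside)
    hit <- findInterval(pos[inside], brk, rightmost.closed = FALSE)
    tab <- tabulate(hit, nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  out <- dplyr::mutate(bins, cell_id = cell_id, count = counts)
  attr(out, "n_skipped") <- skipped
  out
}

#' GC-correct bin counts with a locally weighted regression
#'
#' Fits `lowess(count ~ gc)` and rescales each bin by the ratio of the global
#' mean fitted value to its own fitted value, so the GC trend is flattened
#' while the overall mean count is preserved.
#'
#' @param counts A `bin_counts` tibble (needs `count` and `gc` columns).
#' @param span Lowess span (fraction of points; default 0.3).
#'
#' @return The input tibble with a `corrected` column added.
#' @export
gc_normalize <- function(counts, span = 0.3) {
  stopifnot(all(c("count", "gc") %in% names(counts)))
  if (all(counts$count == 0)) stop("all bin counts are zero")
  if (sum(counts$count > 0) < 50) {
    stop("need at least 50 bins with positive counts for GC correction")
  }
  fit <- stats::lowess(counts$gc, counts$count, f = span)
  fitted <- stats::approx(fit$x, fit$y, xout = counts$gc, rule = 2, ties = mean)$y
  fitted <- pmax(fitted, 1e-8 * mean(counts$count))
  corrected <- counts$count * mean(fitted) / fitted
  # enforce exact mean preservation
  corrected <- corrected * mean(counts$count) / mean(corrected)
  dplyr::mutate(counts, corrected = corrected)
}

#' Convert corrected bin counts to copy-number ratios
#'
#' Ratios are corrected counts divided by their sample mean, so the track
#' averages exactly 1. Computes MAPD alongside (see [mapd()]).
#'
#' @param counts A tibble with a `corrected` column (from [gc_normalize()]);
#'   falls back to `count` when no correction has been applied.
#'
#' @return A `ratio_track` tibble with a `ratio` column and attributes
#'   `mapd` and `cell_id`.
#' @export
to_ratios <- function(counts) {
  x <- if ("corrected" %in% names(counts)) counts$corrected else counts$count
  m <- mean(x)
  if (!is.finite(m) || m <= 0) stop("mean corrected count must be positive")
  out <- dplyr::mutate(counts, ratio = x / m)
  attr(out, "mapd") <- mapd(out)
  attr(out, "cell_id") <- if ("cell_id" %in% names(out)) out$cell_id[1] else NA_character_
  out
}

#' Mean absolute pairwise difference of a ratio track
#'
#' The per-cell noise statistic: the mean, over adjacent bin pairs within the
#' same chromosome, of the absolute difference in ratio. Cells pass QC when
#' MAPD is at or below `threshold`.
#'
#' @param ratios A tibble with `chrom` and `ratio` columns, or a bare numeric
#'   vector (treated as a single chromosome).
#' @param threshold QC threshold (default 0.45).
#'
#' @return A numeric MAPD value with attribute `qc_pass`.
#' @export
mapd <- function(ratios, threshold = 0.45) {
  if (is.numeric(ratios)) {
    ratios <- tibble::tibble(chrom = "1", ratio = ratios)
  }
  stopifnot(all(c("chrom", "ratio") %in% names(ratios)))
  if (nrow(ratios) < 2) stop("MAPD needs at least 2 bins")
  diffs <- unlist(lapply(split(ratios$ratio, factor(ratios$chrom, unique(ratios$chrom))),
                         function(r) if (length(r) >= 2) abs(diff(r)) else numeric(0)))
  if (length(diffs) == 0) stop("no adjacent within-chromosome bin pairs")
  m <- mean(diffs)
  attr(m, "qc_pass") <- m <= threshold
  m
}
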