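#' Segment a copy-number ratio track with circular binary segmentation
#'
#' Native CBS: per chromosome, log2 ratios are scanned for the
#' maximally-contrasting arc; its significance is assessed by a permutation
#' test (max arc statistic, early stopping), and significant splits are
#' applied recursively. Adjacent segments whose standardized mean difference
#' falls below `undo_sd` residual standard deviations are then merged back
#' ("undo"), which removes over-fitted splits in noisy tracks.
#'
#' The same permutation seed is used for every chromosome, so identical
#' chromosomes always segment identically.
#'
#' @param ratios A `ratio_track` tibble (columns `chrom`, `start`, `end`,
#'   `ratio`) from [to_ratios()].
#' @param alpha Permutation significance level for a split (default 0.0001).
#' @param nperm Maximum permutations per split test (default 10000).
#' @param undo_sd Merge adjacent segments whose means differ by less than
#'   this many residual standard deviations (default 1).
#' @param seed Permutation seed (default 7).
#' @param min_ratio Floor applied to ratios before taking log2.
#'
#' @return A tibble of segments: `chrom`, `start_bin`, `end_bin` (1-based bin
#'   indices within chromosome, inclusive), `start`, `end` (bp, 0-based
#'   half-open), `n_bins`, `mean_log2`.
#' @export
segment_cbs <- function(ratios, alpha = 1e-4, nperm = 10000, undo_sd = 1,
                        seed = 7, min_ratio = 1e-3) {
  stopifnot(all(c("chrom", "start", "end", "ratio") %in% names(ratios)))
  chroms <- unique(ratios$chrom)
  purrr::map_dfr(chroms, function(ch) {
    sub <- ratios[ratios$chrom == ch, ]
    x <- log2(pmax(sub$ratio, min_ratio))
    set.seed(seed)
    bounds <- cbs_recurse(x, alpha, nperm)
    bounds <- cbs_undo(x, bounds, undo_sd)
    bounds <- cbs_refine(x, bounds)
    starts <- c(0L, bounds) + 1L
    ends <- c(bounds, length(x))
    tibble::tibble(
      chrom = ch,
      start_bin = starts,
      end_bin = ends,
      start = sub$start[starts],
      end = sub$end[ends],
      n_bins = ends - starts + 1L,
      mean_log2 = purrr::map2_dbl(starts, ends, ~ mean(x[.x:.y]))
    )
  })
}

# Recursive binary splitting; returns sorted internal boundaries (counts of
# bins before each cut) for one chromosome.
cbs_recurse <- function(x, alpha, nperm, offset = 0L) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(integer(0))
  top <- cbs_max_stat(x)
  if (top$stat <= 0) return(integer(0))
  pv <- cbs_perm_pvalue(x, top$stat, nperm, alpha)
  if (pv$p > alpha) return(integer(0))
  cuts <- sort(unique(c(top$i, top$j)))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (length(cuts) == 0) return(integer(0))
  pieces <- Map(function(a, b) x[(a + 1):b],
                c(0L, cuts), c(cuts, n))
  starts <- c(0L, cuts)
  out <- cuts + offset
  for (k in seq_along(pieces)) {
    out <- c(out, cbs_recurse(pieces[[k]], alpha, nperm, offset + starts[k]))
  }
  sort(unique(out))
}

# Merge adjacent segments whose standardized mean difference is below
# undo_sd residual SDs. Residual scale estimated from first differences,
# robust to the segment structure itself.
cbs_undo <- function(x, bounds, undo_sd) {
  if (length(bounds) == 0 || undo_sd <= 0) return(bounds)
  sd_hat <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sd_hat) || sd_hat == 0) sd_hat <- stats::sd(x)
  if (!is.finite(sd_hat) || sd_hat == 0) return(integer(0))
  repeat {
    starts <- c(0L, bounds) + 1L
    ends <- c(bounds, length(x))
    means <- purrr::map2_dbl(starts, ends, ~ mean(x[.x:.y]))
    ns <- ends - starts + 1L
    if (length(means) < 2) return(bounds)
    tstat <- abs(diff(means)) /
      (sd_hat * sqrt(1 / ns[-length(ns)] + 1 / ns[-1]))
    worst <- which.min(tstat)
    if (tstat[worst] >= undo_sd) return(bounds)
    bounds <- bounds[-worst]
    if (length(bounds) == 0) return(bounds)
  }
}

# Local refinement of each internal boundary: holding the neighbouring
# boundaries fixed, re-locate the cut inside the two adjacent segments at
# the position maximizing the standardized mean contrast (the local
# single-changepoint likelihood). Iterated to a fixed point; improves
# localization over the jointly-fitted arcs of the recursion.
cbs_refine <- function(x, bounds, max_iter = 5) {
  if (length(bounds) == 0) return(bounds)
  n <- length(x)
  for (iter in seq_len(max_iter)) {
    prev <- bounds
    for (k in seq_along(bounds)) {
      lo <- if (k == 1) 1L else bounds[k - 1] + 1L
      hi <- if (k == length(bounds)) n else bounds[k + 1]
      w <- x[lo:hi]
      m <- length(w)
      if (m < 2) next
      cs <- cumsum(w)
      n1 <- seq_len(m - 1)
      contrast <- abs(cs[n1] / n1 - (cs[m] - cs[n1]) / (m - n1)) /
        sqrt(1 / n1 + 1 / (m - n1))
      bounds[k] <- lo - 1L + which.max(contrast)
    }
    bounds <- sort(unique(bounds))
    if (identical(bounds, prev)) break
  }
  bounds
}

#' Call gain/loss/neutral states and assemble a CNA profile
#'
#' Segment means are first re-centered on the neutral baseline — the mode of
#' the segment-mean distribution carrying the largest number of bins — and
#' then thresholded into copy-number states.
#'
#' @param segments Segment tibble from [segment_cbs()].
#' @param gain Log2 threshold at or above which a segment is a gain (0.25).
#' @param loss Log2 threshold at or below which a segment is a loss (-0.25).
#' @param center Re-center on the largest-mass segment mode first (default
#'   TRUE).
#' @param autosomes Optional character vector of autosome names; when given,
#'   sex chromosomes are carried through but flagged `autosome = FALSE`.
#'
#' @return A `cna_profile` tibble: segments plus `state`
#'   (loss/neutral/gain) and `autosome`; attribute `baseline` holds the
#'   subtracted center.
#' @export
call_states <- function(segments, gain = 0.25, loss = -0.25, center = TRUE,
                        autosomes = NULL) {
  stopifnot(nrow(segments) > 0, loss < gain)
  baseline <- 0
  if (center) baseline <- neutral_baseline(segments$mean_log2, segments$n_bins)
  centered <- segments$mean_log2 - baseline
  out <- dplyr::mutate(
    segments,
    mean_log2 = centered,
    state = dplyr::case_when(
      centered >= gain ~ "gain",
      centered <= loss ~ "loss",
      TRUE ~ "neutral"
    )
  )
  out$autosome <- if (is.null(autosomes)) {
    !grepl("^(chr)?[XY]$", out$chrom, ignore.case = TRUE)
  } else {
    out$chrom %in% autosomes
  }
  attr(out, "baseline") <- baseline
  class(out) <- c("cna_profile", class(out))
  out
}

# Largest-mass mode of segment means: single-linkage grouping of means
# within `gap`, baseline = bin-weighted mean of the heaviest group.
neutral_baseline <- function(means, weights, gap = 0.1) {
  o <- order(means)
  m <- means[o]; w <- weights[o]
  grp <- cumsum(c(1, diff(m) > gap))
  mass <- tapply(w, grp, sum)
  top <- as.integer(names(mass)[which.max(mass)])
  sum(m[grp == top] * w[grp == top]) / sum(w[grp == top])
}

#' Autosomal CNA burden of a profile
#'
#' The percentage of the autosomal genome covered by segments in a gain or
#' loss state. Sex chromosomes are excluded from both numerator and
#' denominator.
#'
#' @param profile A `cna_profile` from [call_states()].
#' @return Burden in percent (0-100).
#' @export
cna_burden <- function(profile) {
  stopifnot(all(c("start", "end", "state", "autosome") %in% names(profile)))
  auto <- profile[profile$autosome, ]
  if (nrow(auto) == 0) stop("profile has no autosomal segments")
  len <- auto$end - auto$start
  100 * sum(len[auto$state != "neutral"]) / sum(len)
}

#' Full per-cell copy-number profiling pipeline
#'
#' Convenience wrapper: GC-normalize counts, form ratios, compute MAPD QC,
#' segment with CBS, and call states. Used by the malignancy-calling layer
#' and the command-line interface.
#'
#' @param counts A `bin_counts` tibble for one cell.
#' @param mapd_max MAPD QC threshold (default 0.45).
#' @param span Lowess span for GC correction.
#' @param ... Passed to [segment_cbs()] and [call_states()] (`alpha`,
#'   `nperm`, `undo_sd`, `seed`, `gain`, `loss`).
#'
#' @return A `cna_profile` with attributes `mapd`, `qc_pass`, `burden`,
#'   `cell_id`, and `ratios` (the ratio track).
#' @export
cna_profile <- function(counts, mapd_max = 0.45, span = 0.3, ...) {
  dots <- list(...)
  seg_args <- dots[names(dots) %in% c("alpha", "nperm", "undo_sd", "seed", "min_ratio")]
  call_args <- dots[names(dots) %in% c("gain", "loss", "center")]
  ratios <- to_ratios(gc_normalize(counts, span = span))
  m <- mapd(ratios, threshold = mapd_max)
  segs <- do.call(segment_cbs, c(list(ratios), seg_args))
  prof <- do.call(call_states, c(list(segs), call_args))
  attr(prof, "mapd") <- as.numeric(m)
  attr(prof, "qc_pass") <- attr(m, "qc_pass")
  attr(prof, "burden") <- cna_burden(prof)
  attr(prof, "cell_id") <- if ("cell_id" %in% names(counts)) counts$cell_id[1] else NA_character_
  attr(prof, "ratios") <- ratios
  prof
}
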