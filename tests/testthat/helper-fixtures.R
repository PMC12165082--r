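# Shared fixtures. The imaging models are expensive to train, so one
# acceptance-scale training run (fixed seed) is cached and reused by every
# test file in the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture_models <- function() {
  if (is.null(.fixture_cache$models)) {
    .fixture_cache$models <- train_models(n_class_per_group = 400, seed = 11)
  }
  .fixture_cache$models
}

fixture_genome <- function() {
  if (is.null(.fixture_cache$genome)) {
    .fixture_cache$genome <- simulate_bin_gc(
      make_bins(tibble::tibble(chrom = as.character(1:6), length = rep(6e7, 6))),
      seed = 1
    )
  }
  .fixture_cache$genome
}

# Match pipeline records to ground-truth annotations by best IoU.
match_records <- function(records, annotations, min_iou = 0.3) {
  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, c("x", "y", "w", "h")]
    ious <- vapply(seq_len(nrow(annotations)), function(j) {
      iou(r, annotations[j, c("x", "y", "w", "h")])
    }, numeric(1))
    if (length(ious) && max(ious) >= min_iou) {
      annotations$label[which.max(ious)]
    } else "unmatched"
  }, character(1))
}

# Segment tibble builder for concordance tests (bypasses CBS).
toy_profile <- function(means, n_bins = 50, bp_per_bin = 5e5) {
  k <- length(means)
  segs <- tibble::tibble(
    chrom = "1",
    start_bin = seq(1, by = n_bins, length.out = k),
    end_bin = seq(n_bins, by = n_bins, length.out = k),
    start = (seq_len(k) - 1) * n_bins * bp_per_bin,
    end = seq_len(k) * n_bins * bp_per_bin,
    n_bins = rep(n_bins, k),
    mean_log2 = means
  )
  call_states(segs, center = FALSE)
}
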