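# Synthetic inputs for the genomic arm: clonal CNA profiles with GC-biased,
# overdispersed bin counts at a controllable MAPD.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a clone's copy-number events
#'
#' @param events A data frame with columns `chrom`, `start_bin`, `end_bin`
#'   (1-based inclusive bin indices within the chromosome) and `state`
#'   (integer copy number in 0, 1, 3, 4; 2 is the diploid baseline and not
#'   an event). Events must not overlap within a chromosome.
#' @param ploidy Baseline ploidy (default 2).
#' @return A `clone_spec` object.
#' @export
clone_spec <- function(events, ploidy = 2) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("chrom", "start_bin", "end_bin", "state") %in% names(events)))
  if (any(events$state == ploidy)) stop("events must change copy number")
  if (!all(events$state %in% c(0L, 1L, 3L, 4L))) {
    stop("copy states must be in {0, 1, 3, 4}")
  }
  if (any(events$start_bin > events$end_bin)) stop("start_bin must be <= end_bin")
  for (ch in unique(events$chrom)) {
    e <- events[events$chrom == ch, ]
    e <- e[order(e$start_bin), ]
    if (nrow(e) > 1 && any(e$start_bin[-1] <= e$end_bin[-nrow(e)])) {
      stop("events overlap on chromosome ", ch)
    }
  }
  structure(list(events = events, ploidy = ploidy), class = "clone_spec")
}

#' Specify sequencing noise for simulated bin counts
#'
#' Counts are negative-binomial around a GC-biased expectation. The
#' overdispersion can be given directly, or derived from a target MAPD:
#' for near-normal bin ratios the expected MAPD is \eqn{2\sigma_r/\sqrt\pi},
#' so the ratio variance needed for a target \eqn{m} is
#' \eqn{(m\sqrt\pi/2)^2}; the negative-binomial dispersion supplies whatever
#' variance Poisson counting noise at the given depth does not.
#'
#' @param depth Mean reads per diploid bin (must be positive).
#' @param gc_bias Quadratic multiplicative bias coefficients `c(b1, b2)`
#'   applied as `1 + b1*(gc - 0.45) + b2*(gc - 0.45)^2`.
#' @param overdispersion Negative-binomial dispersion phi (var = mu +
#'   phi*mu^2); ignored when `target_mapd` is given.
#' @param target_mapd Desired MAPD of the simulated (GC-corrected) ratio
#'   track; `NULL` together with `overdispersion = NULL` yields
#'   deterministic expected counts.
#' @param seed Seed for this cell's counts.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(depth, gc_bias = c(1.0, -6.0), overdispersion = NULL,
                       target_mapd = NULL, seed = 1) {
  stopifnot(depth > 0, length(gc_bias) == 2)
  if (!is.null(target_mapd)) {
    stopifnot(target_mapd >= 0)
    sigma2 <- (target_mapd * sqrt(pi) / 2)^2
    phi <- sigma2 - 1 / depth
    if (phi < -1e-12) {
      min_mapd <- 2 / sqrt(pi * depth)
      stop(sprintf(
        "target MAPD %.3f unachievable at depth %g: Poisson noise alone gives MAPD ~ %.3f",
        target_mapd, depth, min_mapd
      ))
    }
    overdispersion <- max(phi, 0)
  }
  structure(
    list(depth = depth, gc_bias = gc_bias, overdispersion = overdispersion,
         target_mapd = target_mapd, seed = seed),
    class = "noise_spec"
  )
}

gc_bias_curve <- function(gc, coef) {
  pmax(1 + coef[1] * (gc - 0.45) + coef[2] * (gc - 0.45)^2, 0.05)
}

#' Attach a synthetic GC landscape to genomic bins
#'
#' A smooth quasi-periodic GC profile with mild noise, spanning roughly
#' 0.3-0.6. The periods are short (tens of bins) so GC varies at a finer
#' genomic scale than typical copy-number events; a GC trend confounded
#' with event-scale position would let the lowess correction absorb real
#' copy-number signal.
#'
#' @param bins Bins from [make_bins()].
#' @param seed Seed.
#' @return `bins` with the `gc` column filled.
#' @export
simulate_bin_gc <- function(bins, seed = 1) {
  n <- nrow(bins)
  with_seed(seed, {
    gc <- 0.45 + 0.07 * sin(2 * pi * seq_len(n) / 17) +
      0.05 * sin(2 * pi * seq_len(n) / 37) + stats::rnorm(n, 0, 0.015)
    bins$gc <- pmin(pmax(gc, 0.3), 0.6)
  })
  bins
}

#' Simulate one cell's binned read counts
#'
#' Expected counts are proportional to copy state x depth x GC bias; noise
#' is negative-binomial (Poisson when the dispersion is zero), or absent in
#' the deterministic limit (no dispersion, no target MAPD), in which case
#' the rounded expectation is returned.
#'
#' @param clone A [clone_spec()] or `NULL` for a flat diploid cell.
#' @param bins Bins with GC fractions.
#' @param noise A [noise_spec()].
#' @return A `bin_counts` tibble (integer `count` per bin).
#' @export
simulate_cell_counts <- function(clone = NULL, bins, noise) {
  stopifnot(inherits(noise, "noise_spec"), nrow(bins) > 0, !any(is.na(bins$gc)))
  copy <- rep(if (is.null(clone)) 2 else clone$ploidy, nrow(bins))
  if (!is.null(clone)) {
    for (k in seq_len(nrow(clone$events))) {
      ev <- clone$events[k, ]
      idx <- which(bins$chrom == ev$chrom)
      stopifnot(ev$end_bin <= length(idx))
      copy[idx[ev$start_bin:ev$end_bin]] <- ev$state
    }
  }
  mu <- noise$depth * (copy / 2) * gc_bias_curve(bins$gc, noise$gc_bias)
  counts <- if (is.null(noise$overdispersion) && is.null(noise$target_mapd)) {
    as.integer(round(mu))
  } else {
    phi <- if (is.null(noise$overdispersion)) 0 else noise$overdispersion
    with_seed(noise$seed, {
      if (phi <= 1e-12) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
    })
  }
  out <- dplyr::mutate(bins, cell_id = paste0("cell", noise$seed), count = as.integer(counts))
  attr(out, "true_copy") <- copy
  out
}

#' Simulate a set of cells sharing a clone plus normal cells
#'
#' @param clone A [clone_spec()] planted in the first `n_clone` cells.
#' @param bins Bins with GC fractions.
#' @param n_clone,n_normal Numbers of clonal and flat diploid cells.
#' @param depth,target_mapd Passed to [noise_spec()].
#' @param seed Base seed; cell `i` uses `seed + i`.
#' @return A named list of `bin_counts` tibbles; names carry a
#'   `clone`/`normal` prefix.
#' @export
simulate_cell_set <- function(clone, bins, n_clone, n_normal, depth = 200,
                              target_mapd = 0.3, seed = 1) {
  cells <- list()
  for (i in seq_len(n_clone)) {
    ns <- noise_spec(depth, target_mapd = target_mapd, seed = seed + i)
    cells[[paste0("clone_", i)]] <- simulate_cell_counts(clone, bins, ns)
  }
  for (i in seq_len(n_normal)) {
    ns <- noise_spec(depth, target_mapd = target_mapd, seed = seed + n_clone + i)
    cells[[paste0("normal_", i)]] <- simulate_cell_counts(NULL, bins, ns)
  }
  cells
}
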