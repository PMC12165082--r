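#' Clonal concordance between two CNA profiles
#'
#' Projects each profile's segment means onto bins and correlates the two
#' cells over the union of bins altered (non-neutral) in either cell. Cells
#' without any non-neutral segment are not eligible: the function returns
#' `NA` with a message attribute rather than a score.
#'
#' When both projected vectors vary over the union, the score is the Pearson
#' correlation. When either is constant there (e.g. both cells carry one
#' shared gain and nothing else) Pearson is undefined, and the cosine
#' similarity of the uncentered vectors is used instead — this preserves the
#' required limits of +1 for identical and -1 for mirrored profiles.
#'
#' @param a,b `cna_profile` tibbles from [call_states()] over the same bins.
#' @return A score in \[-1, 1\], or `NA` when either profile is flat.
#' @export
concordance_score <- function(a, b) {
  va <- project_segments(a)
  vb <- project_segments(b)
  if (length(va) != length(vb)) stop("profiles cover different bin sets")
  alt <- project_states(a) != "neutral" | project_states(b) != "neutral"
  if (!any(project_states(a) != "neutral") || !any(project_states(b) != "neutral")) {
    out <- NA_real_
    attr(out, "reason") <- "not eligible: flat profile"
    return(out)
  }
  x <- va[alt]; y <- vb[alt]
  if (stats::sd(x) > 0 && stats::sd(y) > 0) {
    stats::cor(x, y)
  } else {
    sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
  }
}

# Per-bin segment-mean vector of a profile.
project_segments <- function(profile) {
  rep(profile$mean_log2, profile$n_bins)
}

project_states <- function(profile) {
  rep(profile$state, profile$n_bins)
}

#' Label malignant cells by clonal concordance
#'
#' Cells with detectable CNAs (at least one non-neutral segment) are
#' clustered by single linkage on pairwise concordance at or above
#' `score_min`; clusters with at least `min_cluster` members are labeled
#' malignant. Flat cells are always benign.
#'
#' @param profiles Named list of `cna_profile` objects (names = cell ids).
#' @param score_min Concordance threshold for linking two cells (default
#'   0.8).
#' @param min_cluster Minimum clone size to call malignant (default 2).
#'
#' @return A `concordance_result` list with elements `scores` (symmetric
#'   matrix, `NA` where a member is flat), `calls` (tibble: cell_id,
#'   eligible, cluster, malignant), and `malignant_ids`.
#' @export
call_malignant <- function(profiles, score_min = 0.8, min_cluster = 2) {
  stopifnot(length(profiles) >= 2)
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("cell", seq_along(profiles))
  n <- length(profiles)
  eligible <- vapply(profiles, function(p) any(p$state != "neutral"), logical(1))
  scores <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(scores)[eligible] <- 1
  el <- which(eligible)
  if (length(el) >= 2) {
    for (ii in seq_along(el)) {
      for (jj in seq_len(ii - 1)) {
        s <- concordance_score(profiles[[el[ii]]], profiles[[el[jj]]])
        scores[el[ii], el[jj]] <- s
        scores[el[jj], el[ii]] <- s
      }
    }
  }
  # single-linkage connected components over edges score >= score_min
  cluster <- rep(NA_integer_, n)
  if (length(el) > 0) {
    parent <- seq_along(el)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (ii in seq_along(el)) {
      for (jj in seq_len(ii - 1)) {
        s <- scores[el[ii], el[jj]]
        if (!is.na(s) && s >= score_min) {
          ri <- find(ii); rj <- find(jj)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_along(el), find, integer(1))
    cluster[el] <- match(roots, unique(roots))
  }
  sizes <- table(cluster)
  malignant <- !is.na(cluster) &
    cluster %in% as.integer(names(sizes)[sizes >= min_cluster])
  calls <- tibble::tibble(
    cell_id = ids,
    eligible = eligible,
    cluster = cluster,
    malignant = malignant
  )
  structure(
    list(scores = scores, calls = calls, malignant_ids = ids[malignant]),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Clonal concordance result:", nrow(x$calls), "cells,",
      sum(x$calls$eligible), "with detectable CNAs,",
      length(x$malignant_ids), "malignant\n")
  invisible(x)
}
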