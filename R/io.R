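# Configuration and format readers/writers shared by the two arms.

#' Default run configuration
#'
#' Every operating constant of the pipeline as a named default: bin width
#' 500 kb, MAPD QC at 0.45, CBS alpha 1e-4, NMS confidence 0.3 / IoU 0.5,
#' 1024 px patches, 224 px model input, 254/90 px channel crops, 99.8%
#' calibration specificity, and the 0.2% slide cutoff.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A nested list (`run_config`), serializable to YAML/JSON with a
#'   lossless round-trip.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    cna = list(
      bin_width = 5e5, mapd_max = 0.45, alpha = 1e-4, nperm = 10000L,
      undo_sd = 1, gain = 0.25, loss = -0.25, lowess_span = 0.3,
      score_min = 0.8, min_cluster = 2L
    ),
    imaging = list(
      patch_size = 1024L, model_input = 224L, large_crop = 254L,
      small_crop = 90L, conf_min = 0.3, iou_max = 0.5, spec_min = 0.998,
      split = c(0.7, 0.2, 0.1)
    ),
    diagnosis = list(cutoff = 0.2, ci = "clopper-pearson"),
    synthdata = list(
      n_malignant = 6L, n_control = 6L, n_cells = 60L,
      patch_grid = c(2L, 2L), junk_fraction = 0.25,
      depth = 200, target_mapd = 0.3
    )
  )
}

#' Write / read a run configuration
#'
#' YAML round-trip: `read_config(write_config(cfg, path))` is identical to
#' `cfg`.
#'
#' @param config A configuration list.
#' @param path File path (`.yaml`).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write / read per-cell bin counts as BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open), gc, count.
#'
#' @param counts A `bin_counts` tibble.
#' @param path Output TSV path.
#' @export
write_bin_counts <- function(counts, path) {
  readr::write_tsv(counts[, c("chrom", "start", "end", "gc", "count")], path)
  invisible(path)
}

#' @rdname write_bin_counts
#' @param cell_id Cell identifier to attach on read.
#' @export
read_bin_counts <- function(path, cell_id = NULL) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double(),
                           gc = readr::col_double(),
                           count = readr::col_integer()
                         ))
  out$autosome <- !grepl("^(chr)?[XY]$", out$chrom, ignore.case = TRUE)
  out$cell_id <- if (is.null(cell_id)) {
    sub("\\.tsv$", "", basename(path))
  } else cell_id
  out[, c("chrom", "start", "end", "gc", "autosome", "cell_id", "count")]
}

#' Write slide annotations as JSON
#'
#' Boxes are `[x, y, w, h]` in 0-based pixels; masks are run-length
#' encodings; labels are strings.
#'
#' @param annotations Annotation tibble from [render_slide()].
#' @param path Output JSON path.
#' @export
write_annotations <- function(annotations, path) {
  payload <- purrr::pmap(annotations, function(object_id, x, y, w, h, label,
                                               size_class, malignant, is_cell,
                                               mask_rle, ...) {
    list(id = object_id, box = c(x, y, w, h), label = label,
         size_class = size_class, mask = mask_rle)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path)
  purrr::map_dfr(raw, function(o) {
    tibble::tibble(
      object_id = o$id, x = o$box[[1]], y = o$box[[2]],
      w = o$box[[3]], h = o$box[[4]], label = o$label,
      size_class = if (is.null(o$size_class)) NA_character_ else o$size_class,
      malignant = identical(o$label, "malignant"),
      is_cell = o$label %in% c("benign", "malignant"),
      mask_rle = o$mask
    )
  })
}

#' Write / read a cohort table as CSV
#'
#' Columns: patient_id, truth, slide_path, cytology_result.
#'
#' @param cohort Tibble with at least `patient_id` and `truth`.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(c("patient_id", "truth", "slide_path", "cytology_result",
                      "true_etc_fraction", "etc_percent"),
                    names(cohort))
  readr::write_csv(cohort[, keep], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a per-cell CNA profile as TSV (chrom, start, end, log2, state)
#' @param profile A `cna_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  out <- profile[, c("chrom", "start", "end", "mean_log2", "state")]
  names(out)[4] <- "log2"
  readr::write_tsv(out, path)
  invisible(path)
}
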