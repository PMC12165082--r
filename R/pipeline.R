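#' Run the full pipeline end to end on a synthetic cohort
#'
#' Generates a synthetic cohort, trains the imaging models, scores every
#' slide, and produces the cohort diagnostic report. Writes per-slide
#' results, the report, and a manifest recording seeds, thresholds and
#' per-stage counts.
#'
#' @param config A configuration list from [default_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param models Optional pre-trained model list (skips training).
#' @return A list: `cohort` (per-patient tibble with ETC% and calls),
#'   `report` ([cohort_report()]), `models`, `manifest`.
#' @export
run_end_to_end <- function(config = default_config(), out_dir = NULL,
                           models = NULL) {
  stopifnot(is.list(config), !is.null(config$seed))
  sd <- config$synthdata
  if (is.null(models)) {
    models <- train_models(spec_min = config$imaging$spec_min,
                           seed = config$seed)
  }
  cohort <- simulate_cohort(
    n_malignant = sd$n_malignant, n_control = sd$n_control,
    n_cells = sd$n_cells,
    patch_grid = if (is.null(sd$patch_grid)) c(1, 1) else sd$patch_grid,
    junk_fraction = sd$junk_fraction,
    seed = config$seed + 1
  )
  runs <- purrr::map2(cohort$slide, cohort$patient_id, function(sp, id) {
    sl <- render_slide(sp)
    run_slide(sl$wsi, models, cutoff = config$diagnosis$cutoff, slide_id = id)
  })
  results <- purrr::map_dfr(runs, "result")
  cohort_out <- dplyr::bind_cols(
    cohort[, c("patient_id", "truth", "true_etc_fraction")],
    results[, c("n_total_cells", "n_etc", "etc_percent", "call")]
  )
  report <- cohort_report(
    dplyr::transmute(cohort_out, patient_id = .data$patient_id,
                     etc_percent = .data$etc_percent),
    dplyr::transmute(cohort_out, patient_id = .data$patient_id,
                     truth = .data$truth),
    cutoff = config$diagnosis$cutoff
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("etcscreen")),
    seed = config$seed,
    thresholds = list(
      mapd_max = config$cna$mapd_max, cbs_alpha = config$cna$alpha,
      conf_min = config$imaging$conf_min, iou_max = config$imaging$iou_max,
      spec_min = config$imaging$spec_min, cutoff = config$diagnosis$cutoff,
      large_threshold = models$large$threshold,
      small_threshold = models$small$threshold
    ),
    stage_counts = purrr::map_dfr(runs, "stage_counts"),
    n_patients = nrow(cohort_out)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cohort_out, file.path(out_dir, "slide_results.csv"))
    jsonlite::write_json(
      list(metrics = report$model_metrics, table = as.list(report$table)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA
    )
    m <- manifest
    m$stage_counts <- as.list(as.data.frame(m$stage_counts))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort_out, report = report, models = models,
       manifest = manifest)
}
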