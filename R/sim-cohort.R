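#' Simulate a diagnostic cohort of slide specifications
#'
#' Builds a per-patient table with a truth label and a [slide_spec()] whose
#' true ETC fraction is drawn from class-conditional distributions: malignant
#' patients get fractions straddling the 0.2% operating cutoff (log-normal
#' around it), controls are near zero with rare borderline cases.
#'
#' @param n_malignant,n_control Patients per arm (each >= 1).
#' @param n_cells Cells per slide (default 400).
#' @param patch_grid Patch grid per slide (default `c(1, 1)`).
#' @param junk_fraction Junk fraction per slide (default 0.3).
#' @param malignant_meanlog,malignant_sdlog Log-normal parameters (percent
#'   scale) for malignant ETC fractions; the defaults centre near 0.45% with
#'   spread crossing 0.2%.
#' @param control_borderline_rate Probability a control slide carries a
#'   single borderline (non-zero) fraction.
#' @param seed Seed.
#'
#' @return A `cohort_table` tibble: `patient_id`, `truth`
#'   (`"cancer"`/`"control"`), `true_etc_fraction` (percent), and a
#'   list-column `slide` of [slide_spec()] objects.
#' @export
simulate_cohort <- function(n_malignant, n_control, n_cells = 400,
                            patch_grid = c(1, 1), junk_fraction = 0.3,
                            malignant_meanlog = log(0.45),
                            malignant_sdlog = 0.9,
                            control_borderline_rate = 0.1,
                            seed = 1) {
  stopifnot(n_malignant >= 1, n_control >= 1)
  with_seed(seed, {
    frac_mal <- stats::rlnorm(n_malignant, malignant_meanlog, malignant_sdlog)
    frac_mal <- pmin(frac_mal, 100)
    frac_ctl <- ifelse(stats::runif(n_control) < control_borderline_rate,
                       100 / n_cells, 0) # at most one stray positive cell
    truth <- c(rep("cancer", n_malignant), rep("control", n_control))
    fracs <- c(frac_mal, frac_ctl)
    ids <- sprintf("P%03d", seq_along(truth))
    slides <- purrr::map2(fracs, seq_along(fracs), function(f, i) {
      slide_spec(n_cells = n_cells, etc_fraction = f, patch_grid = patch_grid,
                 junk_fraction = junk_fraction, seed = seed * 1000L + i)
    })
    out <- tibble::tibble(
      patient_id = ids, truth = truth,
      true_etc_fraction = fracs, slide = slides
    )
    class(out) <- c("cohort_table", class(out))
    out
  })
}
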