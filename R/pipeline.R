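# End-to-end pipeline driver: synthetic cohort (or marker files) ->
# transfer-function estimates -> group summaries, effect table and figures.

#' Run the full posturography analysis pipeline
#'
#' Generates (or loads) a cohort, estimates per-subject transfer functions,
#' aggregates them into group summaries, fits the factorial ANOVA, and
#' writes tables, figures and a JSON manifest into `out_dir`. Deterministic
#' given `seed`.
#'
#' @param config A list of options; recognised entries (all optional):
#'   `n_per_group` (named vector, default 19/11/17), `noise_sd`,
#'   `subject_sd`, `n_cycles`, plus any other [generate_cohort()] argument.
#' @param out_dir Output directory; created if missing. `NULL` skips writing.
#' @param seed Master seed.
#' @param write_figures Write the gain/phase/coherence spectra and
#'   head-position figure (PDF) alongside the tables.
#' @return A list (invisible when writing): `cohort`, `estimates`,
#'   `summary`, `anova`, `contrasts`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = 1L,
                         write_figures = TRUE) {
  gen_args <- config[intersect(names(config),
                               names(formals(generate_cohort)))]
  gen_args$seed <- seed
  cohort <- do.call(generate_cohort, gen_args)
  estimates <- estimate_cohort(cohort)
  summary <- aggregate_estimates(estimates)
  anova <- factorial_anova(estimates)
  contrasts <- group_contrasts(estimates)

  result <- list(cohort = cohort, estimates = estimates, summary = summary,
                 anova = anova, contrasts = contrasts)
  if (is.null(out_dir)) return(result)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(estimates, file.path(out_dir, "estimates.tsv"))
  readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  readr::write_tsv(tidy(anova), file.path(out_dir, "effects.tsv"))
  readr::write_tsv(contrasts, file.path(out_dir, "contrasts.tsv"))
  jsonlite::write_json(
    list(seed = seed, params = cohort$params,
         n_subjects = length(unique(estimates$subject)),
         n_estimate_rows = nrow(estimates),
         n_summary_rows = nrow(summary)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  if (write_figures) {
    ggplot2::ggsave(file.path(out_dir, "gain_spectra.pdf"),
                    plot_gain_spectra(summary), width = 9, height = 4)
    ggplot2::ggsave(file.path(out_dir, "coherence_spectra.pdf"),
                    plot_gain_spectra(summary, "mean_coherence"),
                    width = 9, height = 4)
    # head-position distribution of one synthetic head track
    head_y <- tibble::tibble(
      time_s = seq_along(cohort$trials$response[[1]]) / 100,
      y_cm = 155 * tan(cohort$trials$response[[1]] * pi / 180)
    )
    ggplot2::ggsave(file.path(out_dir, "head_position.pdf"),
                    plot_head_histogram(head_position_histogram(head_y)),
                    width = 5, height = 4)
  }
  invisible(result)
}
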