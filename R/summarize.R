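# Group-level aggregation of transfer-function estimates: cell means with
# t-based confidence intervals, band-averaged gain-ratio contrasts, and the
# factorial ANOVA over the study design.

#' Aggregate transfer-function estimates into group summaries
#'
#' Per-cell (group x segment x visual x amplitude x frequency) means of gain,
#' phase and coherence across subjects, with t-based 95% confidence-interval
#' half-widths. Cells with a single subject get an `NA` interval; empty cells
#' are simply absent from the output.
#'
#' @param estimates A tibble as returned by [estimate_cohort()] (columns
#'   `subject`, `group`, `segment`, `visual`, `amplitude`, `frequency_hz`,
#'   `gain`, `phase_deg`, `coherence`).
#' @param by Grouping columns for the cells.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A tibble with one row per cell: means, `gain_ci` (half-width),
#'   `phase_ci`, and `n` subjects.
#' @export
aggregate_estimates <- function(estimates,
                                by = c("group", "segment", "visual",
                                       "amplitude", "frequency_hz"),
                                conf_level = 0.95) {
  ci_half <- function(x) {
    n <- sum(is.finite(x))
    if (n < 2L) return(NA_real_)
    stats::qt(1 - (1 - conf_level) / 2, df = n - 1L) *
      stats::sd(x, na.rm = TRUE) / sqrt(n)
  }
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_gain = mean(.data$gain),
      gain_ci = ci_half(.data$gain),
      mean_phase_deg = mean(.data$phase_deg),
      phase_ci = ci_half(.data$phase_deg),
      mean_coherence = mean(.data$coherence),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Band-averaged gain ratio between two groups
#'
#' Ratio of the band-averaged mean gains of two groups for one segment,
#' pooling all other conditions. The 0.15-0.4 Hz mid-band is the default,
#' the band where the PSP head-gain elevation is most pronounced.
#'
#' @param estimates Per-subject estimates as from [estimate_cohort()].
#' @param group_a,group_b Group labels; the ratio is `a / b`.
#' @param band Length-2 numeric, inclusive frequency band in Hz.
#' @param segment Segment to contrast (default `"head"`).
#' @return A single numeric ratio.
#' @examples
#' \dontrun{
#' est <- estimate_cohort(generate_cohort(seed = 1))
#' gain_ratio(est, "PSP", "CTR")  # ~5 by construction of the presets
#' }
#' @export
gain_ratio <- function(estimates, group_a, group_b, band = c(0.15, 0.4),
                       segment = "head") {
  sel <- estimates$segment == segment &
    estimates$frequency_hz >= band[1] - 1e-9 &
    estimates$frequency_hz <= band[2] + 1e-9
  a <- estimates$gain[sel & estimates$group == group_a]
  b <- estimates$gain[sel & estimates$group == group_b]
  if (length(a) == 0L || length(b) == 0L)
    stop("No estimates for the requested groups in the band.", call. = FALSE)
  mb <- mean(b)
  if (mb == 0) stop("Zero mean gain in the denominator group.", call. = FALSE)
  mean(a) / mb
}

#' Factorial ANOVA of gain estimates over the study design
#'
#' Two-stratum (repeated-measures) analysis of variance with group as the
#' between-subjects factor and segment, visual condition, stimulus amplitude
#' and stimulus frequency as within-subject factors, subject as the error
#' stratum. The tested effects are the main effects plus the interactions of
#' interest (group:segment, group:frequency, group:visual, group:amplitude,
#' group:segment:visual by default). Requires a balanced layout; unbalanced
#' input is an error directing the user to cell-mean preprocessing.
#'
#' @param estimates Per-subject estimates (one row per subject x cell) with a
#'   numeric `response` column named by `response`.
#' @param response Name of the response column (default `"gain"`).
#' @param between Between-subjects factor (default `"group"`).
#' @param within Within-subject factors present in the data.
#' @param interactions Character vector of interaction terms to include, in
#'   formula syntax.
#' @param subject Subject identifier column.
#' @return A tibble of class `sway_anova`: `effect`, `df`, `df_error`,
#'   `statistic` (F), `p.value`, `stratum`.
#' @export
factorial_anova <- function(estimates,
                            response = "gain",
                            between = "group",
                            within = c("segment", "visual", "amplitude",
                                       "frequency_hz"),
                            interactions = c("group:segment",
                                             "group:frequency_hz",
                                             "group:visual",
                                             "group:amplitude",
                                             "segment:visual",
                                             "group:segment:visual"),
                            subject = "subject") {
  within <- intersect(within, names(estimates))
  factors <- c(between, within)
  df <- estimates
  for (f in factors) df[[f]] <- factor(df[[f]])
  df$.subj <- factor(df[[subject]])
  df$.y <- df[[response]]

  counts <- table(df[factors])
  if (length(unique(as.vector(counts))) != 1L)
    stop("Unbalanced factorial layout (unequal cell counts). Aggregate to ",
         "cell means per subject before calling factorial_anova().",
         call. = FALSE)

  interactions <- interactions[vapply(strsplit(interactions, ":"), function(tt)
    all(tt %in% factors), logical(1))]
  rhs <- paste(c(factors, interactions), collapse = " + ")
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + Error(.subj)"))
  fit <- stats::aov(form, data = df)

  out <- purrr::imap(summary(fit), function(s, stratum) {
    tab <- as.data.frame(s[[1]])
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    if (!any(keep)) return(NULL)
    resid_df <- tab$Df[eff == "Residuals"]
    tibble::tibble(
      effect = eff[keep],
      df = tab$Df[keep],
      df_error = if (length(resid_df) == 1L) resid_df else NA_real_,
      statistic = tab$`F value`[keep],
      p.value = tab$`Pr(>F)`[keep],
      stratum = gsub("^Error: ", "", stratum)
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("sway_anova", class(out))
  out
}

#' Bonferroni-adjusted pairwise group contrasts of band-averaged gain
#'
#' Welch t-tests of per-subject band-averaged gain between all group pairs,
#' with Bonferroni correction over the family of contrasts
#' (`p_adj = min(1, m p)`).
#'
#' @param estimates Per-subject estimates as from [estimate_cohort()].
#' @param band Frequency band averaged per subject before testing.
#' @param segment Segment to contrast.
#' @return A tibble `group_a`, `group_b`, `estimate` (difference of means),
#'   `statistic`, `p.value`, `p.adjusted`.
#' @export
group_contrasts <- function(estimates, band = c(0.15, 0.4), segment = "head") {
  per_subj <- estimates |>
    dplyr::filter(.data$segment == !!segment,
                  .data$frequency_hz >= band[1] - 1e-9,
                  .data$frequency_hz <= band[2] + 1e-9) |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::summarise(gain = mean(.data$gain), .groups = "drop")
  groups <- unique(per_subj$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  res <- purrr::map(pairs, function(p) {
    a <- per_subj$gain[per_subj$group == p[1]]
    b <- per_subj$gain[per_subj$group == p[2]]
    tt <- stats::t.test(a, b)
    tibble::tibble(group_a = p[1], group_b = p[2],
                   estimate = mean(a) - mean(b),
                   statistic = unname(tt$statistic),
                   p.value = tt$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$p.adjusted <- pmin(1, out$p.value * nrow(out))
  out
}
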