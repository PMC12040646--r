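toy_estimates <- function(gains_by_subject) {
  # minimal estimates table: one segment/visual/amplitude cell, 2 frequencies
  purrr::imap_dfr(gains_by_subject, function(g, subj) {
    tibble::tibble(subject = subj, group = attr(gains_by_subject, "group")[[subj]],
                   segment = "head", visual = "EO", amplitude = 0.5,
                   frequency_hz = c(0.15, 0.3), gain = g,
                   phase_deg = -10, coherence = 0.9)
  })
}

test_that("cell aggregation gives exact t-based confidence intervals", {
  g <- 1.4; d <- 0.2
  gains <- list(S1 = c(g - d, g - d), S2 = c(g + d, g + d))
  attr(gains, "group") <- list(S1 = "CTR", S2 = "CTR")
  agg <- aggregate_estimates(toy_estimates(gains))
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$mean_gain, c(g, g))
  # closed-form t interval for two points g +/- d: half-width t_{.975,1} * d
  expect_equal(agg$gain_ci, rep(stats::qt(0.975, 1) * d, 2), tolerance = 1e-10)
  # identical subjects collapse the interval to zero
  same <- list(S1 = c(g, g), S2 = c(g, g))
  attr(same, "group") <- list(S1 = "CTR", S2 = "CTR")
  agg0 <- aggregate_estimates(toy_estimates(same))
  expect_equal(agg0$gain_ci, c(0, 0))
  # a single subject cannot support an interval
  one <- list(S1 = c(g, g))
  attr(one, "group") <- list(S1 = "CTR")
  expect_true(all(is.na(aggregate_estimates(toy_estimates(one))$gain_ci)))
})

test_that("gain_ratio is unity for identical groups and guards its band", {
  gains <- list(S1 = c(2, 2), S2 = c(2, 2), S3 = c(2, 2), S4 = c(2, 2))
  attr(gains, "group") <- list(S1 = "CTR", S2 = "CTR", S3 = "PSP", S4 = "PSP")
  est <- toy_estimates(gains)
  expect_equal(gain_ratio(est, "PSP", "CTR"), 1)
  expect_error(gain_ratio(est, "PSP", "IPD"), "No estimates")
  zero <- est
  zero$gain[zero$group == "CTR"] <- 0
  expect_error(gain_ratio(zero, "PSP", "CTR"), "Zero mean gain")
})

test_that("one-factor F statistic matches hand-computed sums of squares", {
  # two groups, three subjects each, one response per subject
  y_a <- c(1.0, 1.2, 1.4); y_b <- c(2.0, 2.1, 2.5)
  df <- tibble::tibble(
    subject = sprintf("S%d", 1:6),
    group = rep(c("A", "B"), each = 3),
    gain = c(y_a, y_b)
  )
  out <- factorial_anova(df, within = character(0), interactions = character(0))
  # manual decomposition
  gm <- mean(c(y_a, y_b))
  ss_between <- 3 * ((mean(y_a) - gm)^2 + (mean(y_b) - gm)^2)
  ss_within <- sum((y_a - mean(y_a))^2) + sum((y_b - mean(y_b))^2)
  f_manual <- (ss_between / 1) / (ss_within / 4)
  row <- out[out$effect == "group", ]
  expect_equal(row$statistic, f_manual, tolerance = 1e-8)
  expect_equal(row$df, 1)
  expect_equal(row$df_error, 4)
  expect_equal(row$p.value, stats::pf(f_manual, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("the repeated-measures layout yields the factorial degrees of freedom", {
  est <- simulate_null_gain_table(c(CTR = 3L, IPD = 3L, PSP = 3L), seed = 4)
  out <- factorial_anova(est)
  expect_s3_class(out, "sway_anova")
  expect_true(all(out$statistic >= 0))
  expect_true(all(out$p.value >= 0 & out$p.value <= 1))
  get_df <- function(e) out$df[out$effect == e]
  expect_equal(get_df("group"), 2)            # 3 groups
  expect_equal(get_df("segment"), 2)
  expect_equal(get_df("visual"), 1)
  expect_equal(get_df("amplitude"), 1)
  expect_equal(get_df("frequency_hz"), 10)    # 11 frequencies
  expect_equal(get_df("group:segment"), 4)
  expect_equal(get_df("group:frequency_hz"), 20)
  expect_equal(get_df("group:segment:visual"), 4)
  # group is tested in the between-subject stratum
  expect_equal(out$stratum[out$effect == "group"], ".subj")
})

test_that("sums of squares partition on balanced data", {
  est <- simulate_null_gain_table(c(CTR = 3L, IPD = 3L, PSP = 3L), seed = 9)
  for (f in c("group", "segment", "visual", "amplitude", "frequency_hz"))
    est[[f]] <- factor(est[[f]])
  fit <- stats::aov(gain ~ group * segment * visual, data = est)
  tab <- summary(fit)[[1]]
  ss_total <- sum((est$gain - mean(est$gain))^2)
  expect_equal(sum(tab$`Sum Sq`), ss_total, tolerance = 1e-8)
})

test_that("unbalanced layouts are rejected with guidance", {
  est <- simulate_null_gain_table(c(CTR = 3L, IPD = 3L, PSP = 3L), seed = 2)
  expect_error(factorial_anova(est[-1, ]), "Unbalanced")
})

test_that("group contrasts apply the Bonferroni rule", {
  est <- estimate_cohort(generate_cohort(n_per_group = c(CTR = 3L, IPD = 3L,
                                                         PSP = 3L),
                                         seed = 13))
  out <- group_contrasts(est)
  expect_equal(nrow(out), 3L)
  expect_equal(out$p.adjusted, pmin(1, out$p.value * 3))
  expect_true(all(out$p.adjusted >= out$p.value))
})

test_that("the pipeline bundle has the full factorial cardinality", {
  res <- run_pipeline(config = list(n_per_group = c(CTR = 2L, IPD = 2L,
                                                    PSP = 2L)),
                      out_dir = NULL, seed = 3)
  # 3 groups x 3 segments x 2 visual x 2 amplitudes x 11 frequencies
  expect_equal(nrow(res$summary), 396L)
  expect_equal(nrow(res$estimates), 6 * 3 * 2 * 2 * 11)
  expect_true(all(c("cohort", "estimates", "summary", "anova", "contrasts")
                  %in% names(res)))
  # rerun with the same seed reproduces the estimates exactly
  res2 <- run_pipeline(config = list(n_per_group = c(CTR = 2L, IPD = 2L,
                                                     PSP = 2L)),
                       out_dir = NULL, seed = 3)
  expect_identical(res$estimates, res2$estimates)
})

test_that("the pipeline writes tables, figures and a manifest", {
  out_dir <- withr::local_tempdir()
  run_pipeline(config = list(n_per_group = c(CTR = 2L, IPD = 2L, PSP = 2L)),
               out_dir = out_dir, seed = 3)
  expect_true(file.exists(file.path(out_dir, "estimates.tsv")))
  expect_true(file.exists(file.path(out_dir, "summary.tsv")))
  expect_true(file.exists(file.path(out_dir, "effects.tsv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir, "gain_spectra.pdf")))
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_equal(manifest$n_summary_rows, 396L)
})

test_that("tidiers and plots expose the standard interfaces", {
  x <- default_trial$position_deg
  est <- estimate_sensitivity(blocks_from_response(x))
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("frequency_hz", "gain", "phase_deg", "coherence",
                     "n_blocks", "n_harmonics"))
  gl <- glance(est)
  expect_equal(gl$n_frequencies, 11L)
  expect_s3_class(autoplot(est), "ggplot")
  est_tbl <- simulate_null_gain_table(c(CTR = 2L, IPD = 2L, PSP = 2L), seed = 1)
  av <- factorial_anova(est_tbl)
  expect_s3_class(tidy(av), "tbl_df")
  expect_true(glance(av)$n_effects > 0)
})
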