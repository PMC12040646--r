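test_that("unit transfer function reproduces the stimulus exactly", {
  resp <- synthesize_response(default_trial, constant_profile(1 + 0i))
  expect_equal(resp$angle_deg, default_trial$position_deg, tolerance = 1e-12)
})

test_that("an arbitrary profile round-trips through the estimator", {
  for (grp in c("CTR", "IPD", "PSP")) {
    p <- ground_truth_profile("shoulder", grp, noise_sd = 0)
    resp <- synthesize_response(default_trial, p)
    est <- estimate_sensitivity(blocks_from_response(resp$angle_deg))
    expect_equal(est$gain, p$gain, tolerance = 1e-6)
    expect_equal(est$phase_deg, p$phase_deg, tolerance = 1e-6)
  }
})

test_that("remnant draws are seed-deterministic and profile-shaped", {
  p <- ground_truth_profile("head", "CTR", noise_sd = 0.1)
  r1 <- synthesize_response(default_trial, p, seed = 7)
  r2 <- synthesize_response(default_trial, p, seed = 7)
  r3 <- synthesize_response(default_trial, p, seed = 8)
  expect_identical(r1$angle_deg, r2$angle_deg)
  expect_false(identical(r1$angle_deg, r3$angle_deg))
})

test_that("group presets satisfy the anatomical and clinical orderings", {
  for (grp in c("CTR", "IPD", "PSP")) {
    gh <- ground_truth_profile("head", grp, noise_sd = 0)$gain
    gs <- ground_truth_profile("shoulder", grp, noise_sd = 0)$gain
    gp <- ground_truth_profile("hip", grp, noise_sd = 0)$gain
    expect_true(all(gh >= gs), label = paste(grp, "head >= shoulder"))
    expect_true(all(gs >= gp), label = paste(grp, "shoulder >= hip"))
  }
  for (seg in c("head", "shoulder", "hip")) {
    g_ctr <- ground_truth_profile(seg, "CTR", noise_sd = 0)$gain
    g_ipd <- ground_truth_profile(seg, "IPD", noise_sd = 0)$gain
    g_psp <- ground_truth_profile(seg, "PSP", noise_sd = 0)$gain
    expect_true(all(g_psp > g_ipd), label = paste(seg, "PSP > IPD"))
    expect_true(all(g_ipd > g_ctr), label = paste(seg, "IPD > CTR"))
  }
  # PSP head gain peaks in the 0.15-0.4 Hz mid-band
  psp <- ground_truth_profile("head", "PSP", noise_sd = 0)
  mid <- psp$gain[psp$frequency_hz >= 0.15 & psp$frequency_hz <= 0.4]
  expect_true(all(mid > psp$gain[psp$frequency_hz == 0.05]))
  expect_true(all(mid > psp$gain[psp$frequency_hz == 2.2]))
  # constructed mid-band head ratios
  ctr <- ground_truth_profile("head", "CTR", noise_sd = 0)
  ipd <- ground_truth_profile("head", "IPD", noise_sd = 0)
  sel <- ctr$frequency_hz >= 0.15 & ctr$frequency_hz <= 0.4
  expect_equal(mean(psp$gain[sel]) / mean(ctr$gain[sel]), 5, tolerance = 1e-10)
  expect_equal(mean(psp$gain[sel]) / mean(ipd$gain[sel]), 2, tolerance = 1e-10)
})

test_that("feedback model matches its analytic frequency response", {
  p1 <- feedback_params(w = 1)
  sim <- simulate_feedback_body(default_trial, p1)
  est <- estimate_sensitivity(blocks_from_response(sim$angle_deg),
                              frequencies = prts_band_table(default_design)$harmonic_hz,
                              band_average = FALSE)
  h_ref <- feedback_frequency_response(p1, est$frequency_hz)
  expect_lt(max(abs(est$gain - Mod(h_ref)) / Mod(h_ref)), 0.03)
})

test_that("sensory weight sets the low-frequency tracking regime", {
  p1 <- feedback_params(w = 1)
  p0 <- feedback_params(w = 0)
  # analytic oracle at the lowest analysis frequency
  expect_gt(Mod(feedback_frequency_response(p1, 0.05)), 0.8)
  expect_lt(Mod(feedback_frequency_response(p1, 0.05)), 1.2)
  expect_lt(Mod(feedback_frequency_response(p0, 0.05)), 0.2)
  # and the simulated loop agrees
  sim1 <- simulate_feedback_body(default_trial, p1)
  g1 <- estimate_sensitivity(blocks_from_response(sim1$angle_deg))$gain[1]
  expect_gt(g1, 0.8); expect_lt(g1, 1.2)
  sim0 <- simulate_feedback_body(default_trial, p0)
  g0 <- estimate_sensitivity(blocks_from_response(sim0$angle_deg))$gain[1]
  expect_lt(g0, 0.2)
  # zero stimulus, zero noise: zero response
  quiet <- simulate_feedback_body(rep(0, 2000), p1)
  expect_equal(max(abs(quiet$angle_deg)), 0)
})

test_that("unstable controller settings are rejected at construction", {
  expect_error(feedback_params(delay = 0.25), "Unstable")
  expect_error(feedback_params(w = 1.5), "0, 1")
})

test_that("marker emission honours geometry, jitter bounds and determinism", {
  ts <- seq(0, 5, 0.01)
  zero <- dplyr::bind_rows(lapply(c("head", "shoulder", "hip"), function(s)
    tibble::tibble(time_s = ts, segment = s, angle_deg = 0)))
  mk <- emit_marker_files(zero, seed = 3)
  expect_setequal(unique(mk$marker_id),
                  c("head_vertex", "head_left", "head_right", "trunk_1",
                    "trunk_2", "trunk_3", "hip", "knee_left", "knee_right"))
  # static markers at geometric positions
  expect_true(all(mk$y_cm == 0))
  expect_equal(unique(mk$z_cm[mk$marker_id == "hip"]), 90)
  expect_equal(unique(mk$x_cm[mk$marker_id == "head_left"]), -4)
  # irregular sampling bounded by the acquisition limits
  ints <- diff(mk$time_s[mk$marker_id == "hip"])
  expect_true(all(ints >= 1 / 200 - 1e-12 & ints <= 1 / 80 + 1e-12))
  # deterministic given the seed
  mk2 <- emit_marker_files(zero, seed = 3)
  expect_identical(mk, mk2)
  expect_false(identical(mk, emit_marker_files(zero, seed = 4)))
})

test_that("a known sinusoidal angle survives the marker round trip", {
  ts <- seq(0, 10, 0.01)
  angles <- dplyr::bind_rows(lapply(c("head", "shoulder", "hip"), function(s)
    tibble::tibble(time_s = ts, segment = s,
                   angle_deg = sin(2 * pi * 0.3 * ts))))
  mk <- emit_marker_files(angles, seed = 21)
  out <- trial_segment_angles(split(mk, mk$marker_id),
                              heights_cm = c(head = 155, shoulder = 130,
                                             hip = 90))
  amp <- sqrt(2) * excursion_amplitude(out[out$segment == "head", ])$rms_deg
  expect_equal(amp, 1, tolerance = 0.02)
})

test_that("marker files round-trip through disk", {
  ts <- seq(0, 2, 0.01)
  angles <- dplyr::bind_rows(lapply(c("head", "shoulder", "hip"), function(s)
    tibble::tibble(time_s = ts, segment = s, angle_deg = 0.5 * sin(ts))))
  path <- withr::local_tempfile(fileext = ".tsv")
  emit_marker_files(angles, seed = 1, path = path,
                    metadata = list(group = "CTR", visual = "EO"))
  tracks <- read_marker_file(path)
  expect_length(tracks, 9L)
  expect_true(all(vapply(tracks, function(t) all(diff(t$time_s) > 0),
                         logical(1))))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$group, "CTR")
})

test_that("cohort generation is deterministic and correctly sized", {
  n <- c(CTR = 2L, IPD = 1L, PSP = 2L)
  co <- generate_cohort(n_per_group = n, seed = 5)
  expect_s3_class(co, "sway_cohort")
  # subjects x (2 visual x 2 amplitude x 2 repeats) x 3 segments
  expect_equal(nrow(co$trials), sum(n) * 8 * 3)
  expect_equal(nrow(co$manifest), sum(n) * 3)
  co2 <- generate_cohort(n_per_group = n, seed = 5)
  expect_identical(co$trials$response, co2$trials$response)
  co3 <- generate_cohort(n_per_group = n, seed = 6)
  expect_false(identical(co$trials$response, co3$trials$response))
})

test_that("a noise-free single subject reproduces the group preset", {
  co <- generate_cohort(n_per_group = c(PSP = 1L), seed = 2, noise_sd = 0,
                        subject_sd = 0)
  est <- estimate_cohort(co)
  truth <- dplyr::select(co$truth, "subject", "segment", "visual",
                         "amplitude", "frequency_hz", "true_gain",
                         "true_phase_deg")
  m <- dplyr::inner_join(est, truth,
                         by = c("subject", "segment", "visual", "amplitude",
                                "frequency_hz"))
  expect_equal(m$gain, m$true_gain, tolerance = 1e-6)
  expect_equal(m$phase_deg, m$true_phase_deg, tolerance = 1e-6)
})
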