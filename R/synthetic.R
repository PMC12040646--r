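# Synthetic posturography: ground-truth-known multi-segment sway responses to
# the PRTS stimulus, group-typical gain/phase presets, a delayed-feedback
# inverted-pendulum simulator, and Zebris-like irregular marker files.

# run code with a transient RNG state derived from `seed`
with_seed <- function(seed, code) {
  force(seed)  # evaluate (possibly random) seed before snapshotting the RNG
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Group-typical gain presets at the 11 analysis frequencies. Shapes emulate
# the qualitative findings: head > shoulder > hip at every frequency within
# each group; PSP > IPD > CTR, with the PSP head gain peaking in the 0.15-0.4
# Hz mid-band; low-pass roll-off above ~1 Hz. Head mid-band averages are
# constructed so PSP/CTR = 5 and PSP/IPD = 2 exactly.
PRESET_GAINS <- list(
  CTR = list(
    head     = c(1.00, 1.05, 1.05, 1.00, 0.90, 0.80, 0.70, 0.55, 0.45, 0.35, 0.25),
    shoulder = c(0.90, 0.90, 0.85, 0.80, 0.70, 0.62, 0.55, 0.45, 0.38, 0.30, 0.22),
    hip      = c(0.80, 0.75, 0.70, 0.65, 0.58, 0.50, 0.42, 0.35, 0.28, 0.22, 0.16)
  ),
  IPD = list(
    head     = c(1.80, 2.50, 2.75, 2.50, 2.10, 1.80, 1.50, 1.10, 0.85, 0.65, 0.50),
    shoulder = c(1.20, 1.40, 1.40, 1.30, 1.15, 1.00, 0.85, 0.70, 0.55, 0.42, 0.32),
    hip      = c(1.00, 1.10, 1.05, 1.00, 0.90, 0.78, 0.65, 0.52, 0.42, 0.32, 0.24)
  ),
  PSP = list(
    head     = c(2.50, 5.00, 5.50, 5.00, 4.00, 3.00, 2.20, 1.60, 1.20, 0.90, 0.70),
    shoulder = c(1.60, 2.20, 2.40, 2.20, 1.90, 1.60, 1.30, 1.00, 0.80, 0.60, 0.45),
    hip      = c(1.20, 1.50, 1.60, 1.50, 1.30, 1.10, 0.90, 0.72, 0.56, 0.42, 0.30)
  )
)

# Phase presets (degrees): small anticipatory lead at the lowest frequency,
# lag growing with frequency, more lag in higher segments.
PRESET_PHASE_SLOPES <- c(head = 55, shoulder = 40, hip = 25)
PRESET_PHASE_LEAD <- 8

#' Ground-truth transfer-function profile for a segment and group style
#'
#' Returns the complex transfer function of a synthetic subject archetype at
#' the 11 analysis frequencies, with the additive remnant-noise model used by
#' [synthesize_response()]. Presets encode the qualitative group differences:
#' gain ordering head >= shoulder >= hip within every group, PSP > IPD > CTR
#' between groups, a PSP head-gain peak in the 0.15-0.4 Hz mid-band, and
#' low-pass attenuation above ~1 Hz. Mid-band (0.15-0.4 Hz) head-gain ratios
#' are constructed as PSP/CTR = 5 and PSP/IPD = 2 exactly.
#'
#' @param segment `"head"`, `"shoulder"` or `"hip"`.
#' @param group_style `"CTR"`, `"IPD"` or `"PSP"`.
#' @param noise_sd Standard deviation of the additive remnant sway, degrees.
#' @param remnant_model `"pink"` (1/f, default) or `"white"`.
#' @return A list of class `ground_truth_profile` with fields `segment`,
#'   `group_style`, `frequency_hz`, `gain`, `phase_deg`, `H` (complex),
#'   `noise_sd`, `remnant_model`.
#' @examples
#' p <- ground_truth_profile("head", "PSP")
#' p$gain
#' @export
ground_truth_profile <- function(segment = c("head", "shoulder", "hip"),
                                 group_style = c("CTR", "IPD", "PSP"),
                                 noise_sd = 0.025,
                                 remnant_model = c("pink", "white")) {
  segment <- match.arg(segment)
  group_style <- match.arg(group_style)
  remnant_model <- match.arg(remnant_model)
  f <- PRTS_ANALYSIS_FREQUENCIES
  gain <- PRESET_GAINS[[group_style]][[segment]]
  phase <- PRESET_PHASE_LEAD - PRESET_PHASE_SLOPES[[segment]] * f
  structure(
    list(
      segment = segment,
      group_style = group_style,
      frequency_hz = f,
      gain = gain,
      phase_deg = phase,
      H = gain * exp(1i * phase * pi / 180),
      noise_sd = noise_sd,
      remnant_model = remnant_model
    ),
    class = "ground_truth_profile"
  )
}

# rescale a profile's gain by a scalar (subject heterogeneity, condition
# multipliers); phase is untouched
scale_profile <- function(profile, factor) {
  profile$gain <- profile$gain * factor
  profile$H <- profile$H * factor
  profile
}

#' Synthesize a segment-angle response from a stimulus and a profile
#'
#' Frequency-domain forward model: the stimulus spectrum is multiplied by the
#' profile's complex transfer function and inverse-transformed, then additive
#' remnant noise is drawn with `seed`. The profile specifies H at the 11
#' nominal analysis frequencies; each spectral bin receives the H of the
#' analysis band it falls in (bins beyond the outermost band edges get the
#' nearest band's value), so a noiseless synthesis followed by
#' [estimate_sensitivity()] returns the profile exactly. With zero noise and
#' H = 1 the response equals the stimulus exactly.
#'
#' @param stimulus A `prts_trial` tibble from [build_trial()], or a numeric
#'   vector of platform angle samples at `rate` Hz.
#' @param profile A [ground_truth_profile()].
#' @param seed Integer seed for the remnant draw (deterministic given seed).
#' @param rate Sample rate, Hz, when `stimulus` is a bare vector.
#' @return A tibble `time_s`, `angle_deg`, `segment` (class
#'   `segment_angle_series`).
#' @export
synthesize_response <- function(stimulus, profile, seed = 1L, rate = 100) {
  stopifnot(inherits(profile, "ground_truth_profile"))
  if (inherits(stimulus, "prts_trial")) {
    rate <- attr(stimulus, "design")$sample_rate
    x <- stimulus$position_deg
  } else {
    x <- as.numeric(stimulus)
  }
  n <- length(x)
  freqs <- seq(0, n - 1) / n * rate
  freqs <- ifelse(freqs > rate / 2, freqs - rate, freqs)  # signed frequencies

  h <- profile$H[band_index(freqs, profile$frequency_hz)]
  h[freqs < 0] <- Conj(h[freqs < 0])  # Hermitian symmetry -> real output
  h[1] <- Re(h[1])  # DC stays real

  resp <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
  if (profile$noise_sd > 0) {
    resp <- resp + with_seed(seed, remnant_noise(n, rate, profile$noise_sd,
                                                 profile$remnant_model))
  }
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1L) / rate,
    angle_deg = resp,
    segment = profile$segment
  )
  attr(out, "rate_hz") <- rate
  class(out) <- c("segment_angle_series", class(out))
  out
}

# Broadband remnant sway: white, or pink (amplitude ~ 1/sqrt(f)) shaped in
# the frequency domain; scaled to standard deviation `sd`.
remnant_noise <- function(n, rate, sd, model = c("pink", "white")) {
  model <- match.arg(model)
  if (model == "white") return(stats::rnorm(n, 0, sd))
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- seq(0, n - 1) / n * rate
  f <- pmin(f, rate - f)
  shape <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::fft(spec * shape, inverse = TRUE) / n)
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Parameters of the delayed-feedback inverted-pendulum model
#'
#' A single-link inverted pendulum balanced by a delayed
#' proportional-derivative controller acting on a weighted mix of
#' proprioceptive (body-to-surface) and graviceptive (body-to-space) error.
#' With sensory weight `w = 1` the controller references the tilting surface
#' and the body tracks the platform (low-frequency gain near 1, an egocentric
#' strategy); with `w = 0` it references gravity and the body stays earth
#' vertical (low-frequency gain near 0). Closed-loop stability is validated
#' at construction by simulating the unforced response to a small initial
#' lean and requiring decay.
#'
#' @param mass Body mass above the ankles, kg.
#' @param com_height Height of the centre of mass above the ankle axis, m.
#' @param moment_of_inertia Moment of inertia about the ankle axis, kg m^2;
#'   default `mass * com_height^2 * 4/3` (rod-like distribution).
#' @param kp Proportional feedback gain, N m / rad. Default 8x the
#'   gravitational toppling stiffness `mass * g * com_height`, stiff enough
#'   that the surface-referenced low-frequency gain is close to 1.
#' @param kd Derivative feedback gain, N m s / rad (default `0.35 * kp`).
#' @param delay Lumped sensorimotor delay, s (default 0.05).
#' @param w Sensory weight in [0, 1]: 1 = surface-referenced, 0 =
#'   space-referenced.
#' @return A list of class `feedback_params`.
#' @export
feedback_params <- function(mass = 75, com_height = 0.95,
                            moment_of_inertia = NULL,
                            kp = NULL, kd = NULL, delay = 0.05, w = 1) {
  g <- 9.81
  if (mass <= 0 || com_height <= 0) stop("Mass and CoM height must be positive.",
                                         call. = FALSE)
  if (w < 0 || w > 1) stop("`w` must lie in [0, 1].", call. = FALSE)
  if (is.null(moment_of_inertia)) moment_of_inertia <- mass * com_height^2 * 4 / 3
  mgh <- mass * g * com_height
  if (is.null(kp)) kp <- 8 * mgh
  if (is.null(kd)) kd <- 0.35 * kp
  params <- structure(
    list(mass = mass, com_height = com_height,
         moment_of_inertia = moment_of_inertia,
         mgh = mgh, kp = kp, kd = kd, delay = delay, w = w),
    class = "feedback_params"
  )
  if (!feedback_stable(params))
    stop("Unstable closed loop: the unforced response does not decay. ",
         "Adjust kp/kd/delay.", call. = FALSE)
  params
}

# simulate 10 s of unforced response to a 1-degree lean; stable if the final
# 2 s envelope is below half the initial lean
feedback_stable <- function(params) {
  th <- simulate_feedback_core(numeric(1000), params, rate = 100,
                               theta0 = 1 * pi / 180)
  max(abs(th[801:1000])) < 0.5 * pi / 180
}

# Fixed-step (semi-implicit Euler) integration of
#   J theta'' = mgh theta - (Kp e(t - tau) + Kd e'(t - tau))
#   e = w (theta - p) + (1 - w) theta
# Delayed terms are read from the computed history (zero before t = 0). The
# loop runs at `substeps` times the output rate for accuracy; the platform
# command is linearly interpolated onto the fine grid.
simulate_feedback_core <- function(platform_rad, params, rate,
                                   theta0 = 0, substeps = 8L) {
  n_out <- length(platform_rad)
  fine <- rate * substeps
  n <- n_out * substeps
  p <- stats::approx(seq_len(n_out), platform_rad,
                     xout = seq(1, n_out, length.out = n), rule = 2)$y
  dt <- 1 / fine
  d_steps <- as.integer(round(params$delay * fine))
  th <- numeric(n); om <- numeric(n)
  e <- numeric(n); de <- numeric(n)
  th[1] <- theta0
  dp <- c(0, diff(p)) * fine
  J <- params$moment_of_inertia
  for (k in seq_len(n - 1L)) {
    e[k] <- params$w * (th[k] - p[k]) + (1 - params$w) * th[k]
    de[k] <- params$w * (om[k] - dp[k]) + (1 - params$w) * om[k]
    kd_idx <- k - d_steps
    e_d <- if (kd_idx >= 1L) e[kd_idx] else 0
    de_d <- if (kd_idx >= 1L) de[kd_idx] else 0
    torque <- params$mgh * th[k] - params$kp * e_d - params$kd * de_d
    om[k + 1L] <- om[k] + dt * torque / J
    th[k + 1L] <- th[k] + dt * om[k + 1L]
  }
  th[seq(1L, n, by = substeps)]
}

#' Simulate body sway with the delayed-feedback pendulum model
#'
#' Numerically integrates the linearised delay-differential model of
#' [feedback_params()] driven by the platform tilt, returning the
#' body-in-space sway angle. The analytic frequency response of the same
#' model is available from [feedback_frequency_response()].
#'
#' @param stimulus A `prts_trial` or numeric vector of platform tilt, degrees.
#' @param params A [feedback_params()] object.
#' @param seed Seed for the optional remnant noise.
#' @param noise_sd Additive remnant noise sd, degrees (0 = deterministic).
#' @param rate Sample rate, Hz, when `stimulus` is a bare vector.
#' @param settle_s Lead-in time prepended (and discarded) so the delayed
#'   feedback reaches steady state before the reported epoch, seconds.
#' @return A tibble `time_s`, `angle_deg`, `segment = "body"` (class
#'   `segment_angle_series`).
#' @export
simulate_feedback_body <- function(stimulus, params, seed = 1L, noise_sd = 0,
                                   rate = 100, settle_s = 20) {
  stopifnot(inherits(params, "feedback_params"))
  if (inherits(stimulus, "prts_trial")) {
    rate <- attr(stimulus, "design")$sample_rate
    x <- stimulus$position_deg
  } else {
    x <- as.numeric(stimulus)
  }
  n <- length(x)
  n_settle <- as.integer(round(settle_s * rate))
  # periodic lead-in: recycle the stimulus tail so the loop is warm
  lead <- if (n_settle > 0L) rep_len(x, n_settle + n)[seq_len(n_settle)] else numeric(0)
  th <- simulate_feedback_core(c(lead, x) * pi / 180, params, rate)
  resp <- th[(n_settle + 1L):(n_settle + n)] * 180 / pi
  if (noise_sd > 0) resp <- resp + with_seed(seed, remnant_noise(n, rate, noise_sd, "pink"))
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1L) / rate,
    angle_deg = resp,
    segment = "body"
  )
  attr(out, "rate_hz") <- rate
  class(out) <- c("segment_angle_series", class(out))
  out
}

#' Analytic frequency response of the delayed-feedback pendulum
#'
#' Closed-form transfer function from platform tilt to body-in-space angle:
#' `H(s) = w (Kp + Kd s) e^(-s tau) / (J s^2 - mgh + (Kp + Kd s) e^(-s tau))`
#' evaluated at `s = 2 pi i f`. Serves as the exact reference for the
#' time-domain simulator.
#'
#' @param params A [feedback_params()] object.
#' @param frequencies Frequencies, Hz.
#' @return Complex vector of the frequency response.
#' @export
feedback_frequency_response <- function(params,
                                        frequencies = PRTS_ANALYSIS_FREQUENCIES) {
  stopifnot(inherits(params, "feedback_params"))
  s <- 2i * pi * frequencies
  num <- params$w * (params$kp + params$kd * s) * exp(-s * params$delay)
  den <- params$moment_of_inertia * s^2 - params$mgh +
    (params$kp + params$kd * s) * exp(-s * params$delay)
  num / den
}

# Default marker geometry (heights above the ankle axis, cm; lateral offsets,
# cm) for a ~1.75 m subject.
default_geometry <- function() {
  list(
    heights_cm = c(head = 155, shoulder = 130, hip = 90, knee = 45),
    lateral_offset_cm = 4,
    trunk_spacing_cm = 8
  )
}

#' Emit Zebris-like raw marker files from segment-angle series
#'
#' Forward kinematics from head/shoulder/hip sway angles to 9 marker tracks
#' (3 head, 3 trunk, 1 hip, 2 knee) with irregular timestamps emulating the
#' dynamic 80-200 Hz acquisition (inter-sample intervals uniform in
#' [1/200, 1/80] s). The anteroposterior excursion of each marker is
#' `h * tan(angle)` about its quiet-stance position, so the kinematics module
#' recovers the generating angles by construction. Left/right pairs are
#' offset laterally. Optionally writes the long-format delimited file and a
#' JSON metadata sidecar that [read_marker_file()] and the pipeline consume.
#'
#' @param angles A data frame with `time_s`, `segment` (head/shoulder/hip),
#'   `angle_deg` — e.g. rows from [synthesize_response()] bound together.
#' @param geometry Marker geometry list (`heights_cm`, `lateral_offset_cm`,
#'   `trunk_spacing_cm`); default [default_geometry()] values.
#' @param seed Seed for the timestamp jitter.
#' @param path Optional output path for the marker table (TSV).
#' @param metadata Optional named list written as a JSON sidecar next to
#'   `path` (`<path>.json`).
#' @return The long-format marker tibble, invisibly if `path` is given.
#' @export
emit_marker_files <- function(angles, geometry = default_geometry(), seed = 1L,
                              path = NULL, metadata = NULL) {
  segs <- c("head", "shoulder", "hip")
  ang <- list()
  for (s in segs) {
    a <- angles[angles$segment == s, ]
    if (nrow(a) == 0L) stop("`angles` is missing segment: ", s, call. = FALSE)
    ang[[s]] <- a
  }
  t_grid <- ang$head$time_s
  span <- range(t_grid)
  h <- geometry$heights_cm
  off <- geometry$lateral_offset_cm
  spc <- geometry$trunk_spacing_cm

  # marker -> (segment, height above ankle, lateral x)
  layout <- tibble::tibble(
    marker_id = c("head_vertex", "head_left", "head_right",
                  "trunk_1", "trunk_2", "trunk_3",
                  "hip", "knee_left", "knee_right"),
    segment = c("head", "head", "head", "shoulder", "shoulder", "shoulder",
                "hip", "knee", "knee"),
    height_cm = c(h[["head"]] + 5, h[["head"]], h[["head"]],
                  h[["shoulder"]], h[["shoulder"]], h[["shoulder"]],
                  h[["hip"]], h[["knee"]], h[["knee"]]),
    x_cm = c(0, -off, off, -spc, 0, spc, 0, -off, off)
  )

  with_seed(seed, {
    rows <- purrr::pmap(layout, function(marker_id, segment, height_cm, x_cm) {
      # irregular acquisition: intervals uniform in [1/200, 1/80] s
      ts <- span[1]
      while (dplyr::last(ts) < span[2])
        ts <- c(ts, dplyr::last(ts) + stats::runif(1, 1 / 200, 1 / 80))
      ts <- ts[ts <= span[2]]
      theta <- if (segment == "knee") numeric(length(ts)) else
        stats::approx(t_grid, ang[[segment]]$angle_deg, xout = ts, rule = 2)$y
      tibble::tibble(
        time_s = ts,
        marker_id = marker_id,
        x_cm = x_cm,
        y_cm = height_cm * tan(theta * pi / 180),
        z_cm = height_cm
      )
    })
    out <- dplyr::bind_rows(rows)
    if (!is.null(path)) {
      readr::write_tsv(out, path)
      if (!is.null(metadata))
        jsonlite::write_json(metadata, paste0(path, ".json"),
                             auto_unbox = TRUE, pretty = TRUE)
      return(invisible(out))
    }
    out
  })
}

#' Generate a full synthetic study cohort
#'
#' Builds a ground-truth-known study: per subject and condition (eyes
#' open/closed x 0.5/1 degree tilt, each condition recorded twice), responses
#' of the head, shoulder and hip segments to the PRTS stimulus are
#' synthesized from the subject's group preset scaled by a subject-level
#' log-normal gain perturbation and condition multipliers. Default cohort
#' sizes are 19 CTR, 11 IPD, 17 PSP. Deterministic given `seed`.
#'
#' @param n_per_group Named integer vector of subjects per group.
#' @param seed Master seed; all subject, condition and noise draws derive
#'   from it.
#' @param noise_sd Remnant noise sd, degrees (applies to every trial).
#' @param subject_sd Log-scale sd of the per-subject, per-segment gain
#'   multiplier (0 disables heterogeneity).
#' @param ec_factor Gain multiplier of the eyes-closed condition.
#' @param low_amp_factor Gain multiplier of the 0.5-degree condition relative
#'   to 1 degree.
#' @param n_cycles Stimulus cycles per trial (default 3 = 60 s).
#' @param remnant_model Remnant noise model (`"pink"` or `"white"`).
#' @return A list of class `sway_cohort`: `trials` (tibble with one row per
#'   subject x condition x repeat x segment, response in a list-column),
#'   `manifest` (per subject x segment ground-truth gain multipliers and true
#'   per-condition gains), `stimulus` (list of `prts_trial` per amplitude),
#'   and the generation parameters.
#' @examples
#' co <- generate_cohort(n_per_group = c(CTR = 2, IPD = 2, PSP = 2), seed = 1)
#' nrow(co$trials)  # 2*3 subjects x 8 trials x 3 segments
#' @export
generate_cohort <- function(n_per_group = c(CTR = 19L, IPD = 11L, PSP = 17L),
                            seed = 1L,
                            noise_sd = 0.025,
                            subject_sd = 0.2,
                            ec_factor = 1.12,
                            low_amp_factor = 1.15,
                            n_cycles = 3L,
                            remnant_model = "pink") {
  stopifnot(all(n_per_group >= 1L))
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% c("CTR", "IPD", "PSP")))
    stop("`n_per_group` must be named with groups CTR/IPD/PSP.", call. = FALSE)

  stimulus <- lapply(c("0.5" = 0.5, "1" = 1), function(amp) {
    d <- prts_design(peak_amplitude = amp)
    build_trial(states_to_position(generate_prts_states(d), d), n_cycles)
  })

  conditions <- tidyr::expand_grid(
    visual = c("EO", "EC"),
    amplitude = c(0.5, 1),
    rep = 1:2
  )
  segs <- c("head", "shoulder", "hip")

  subjects <- tibble::tibble(
    group = rep(groups, times = n_per_group),
    subject = sprintf("S%03d", seq_len(sum(n_per_group)))
  )

  # per-subject, per-segment multiplicative gain perturbation (log-normal)
  mult <- with_seed(seed, {
    m <- matrix(exp(stats::rnorm(nrow(subjects) * length(segs), 0, subject_sd)),
                nrow = nrow(subjects))
    dimnames(m) <- list(subjects$subject, segs)
    m
  })

  manifest <- tidyr::expand_grid(subjects, segment = segs) |>
    dplyr::mutate(gain_multiplier = mult[cbind(.data$subject, .data$segment)])

  trial_rows <- tidyr::expand_grid(subjects, conditions, segment = segs)
  trial_rows$trial_seed <- (seed * 10000L +
                              as.integer(factor(trial_rows$subject)) * 97L +
                              match(trial_rows$segment, segs) * 13L +
                              match(trial_rows$visual, c("EO", "EC")) * 5L +
                              match(trial_rows$amplitude, c(0.5, 1)) * 3L +
                              trial_rows$rep) %% .Machine$integer.max

  trial_rows$response <- purrr::pmap(
    trial_rows[c("group", "subject", "visual", "amplitude", "segment",
                 "trial_seed")],
    function(group, subject, visual, amplitude, segment, trial_seed) {
      prof <- ground_truth_profile(segment, group, noise_sd = noise_sd,
                                   remnant_model = remnant_model)
      fct <- mult[subject, segment] *
        (if (visual == "EC") ec_factor else 1) *
        (if (amplitude == 0.5) low_amp_factor else 1)
      stim <- stimulus[[as.character(amplitude)]]
      synthesize_response(stim, scale_profile(prof, fct),
                          seed = trial_seed)$angle_deg
    }
  )

  # true per-condition gains for parameter-recovery checks
  truth <- tidyr::expand_grid(subjects,
                              visual = c("EO", "EC"), amplitude = c(0.5, 1),
                              segment = segs,
                              frequency_hz = PRTS_ANALYSIS_FREQUENCIES)
  truth <- dplyr::mutate(
    dplyr::rowwise(truth),
    true_gain = PRESET_GAINS[[.data$group]][[.data$segment]][
      match(.data$frequency_hz, PRTS_ANALYSIS_FREQUENCIES)] *
      mult[.data$subject, .data$segment] *
      (if (.data$visual == "EC") ec_factor else 1) *
      (if (.data$amplitude == 0.5) low_amp_factor else 1),
    true_phase_deg = PRESET_PHASE_LEAD -
      PRESET_PHASE_SLOPES[[.data$segment]] * .data$frequency_hz
  ) |> dplyr::ungroup()

  structure(
    list(
      trials = trial_rows,
      manifest = manifest,
      truth = truth,
      stimulus = stimulus,
      params = list(seed = seed, noise_sd = noise_sd, subject_sd = subject_sd,
                    ec_factor = ec_factor, low_amp_factor = low_amp_factor,
                    n_cycles = n_cycles, remnant_model = remnant_model,
                    n_per_group = as.list(n_per_group))
    ),
    class = "sway_cohort"
  )
}

#' @export
print.sway_cohort <- function(x, ...) {
  n <- table(x$trials$group[!duplicated(x$trials$subject)])
  cat("<sway_cohort> ", sum(n), " subjects (",
      paste(names(n), n, sep = "=", collapse = ", "), "), ",
      nrow(x$trials), " trial-segment series\n", sep = "")
  invisible(x)
}

#' Estimate transfer functions for every subject and condition of a cohort
#'
#' Runs the spectral pipeline over a synthetic (or equivalently structured)
#' cohort: for each subject x segment x visual x amplitude cell, the two
#' repeat trials are segmented into stimulus-period blocks (first cycle of
#' each trial discarded) and the sensitivity function and coherence are
#' estimated.
#'
#' @param cohort A `sway_cohort` from [generate_cohort()].
#' @return A tibble with one row per subject x segment x condition x
#'   frequency: `subject`, `group`, `segment`, `visual`, `amplitude`,
#'   `frequency_hz`, `gain`, `phase_deg`, `coherence`, `n_blocks`.
#' @export
estimate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "sway_cohort"))
  tr <- cohort$trials
  keys <- dplyr::distinct(tr, .data$subject, .data$group, .data$segment,
                          .data$visual, .data$amplitude)
  res <- purrr::pmap(keys, function(subject, group, segment, visual, amplitude) {
    sel <- tr$subject == subject & tr$segment == segment &
      tr$visual == visual & tr$amplitude == amplitude
    stim <- cohort$stimulus[[as.character(amplitude)]]$position_deg
    trials <- lapply(tr$response[sel], function(resp)
      data.frame(stimulus = stim, response = resp))
    est <- tidy(estimate_sensitivity(segment_blocks(trials)))
    dplyr::bind_cols(
      tibble::tibble(subject = rep(subject, nrow(est)), group, segment,
                     visual, amplitude),
      est
    )
  })
  dplyr::bind_rows(res)
}

#' Null gain table for calibration studies
#'
#' A balanced factorial layout (group x segment x visual x amplitude x
#' frequency, per subject) whose response is pure i.i.d. Gaussian noise with
#' no effect of any factor — the null reference for checking the type-I error
#' rate of [factorial_anova()].
#'
#' @param n_per_group Subjects per group.
#' @param seed RNG seed.
#' @param sd Noise sd of the response.
#' @return A tibble in the shape returned by [estimate_cohort()], with a
#'   `gain` response carrying no factor effects.
#' @export
simulate_null_gain_table <- function(n_per_group = c(CTR = 5L, IPD = 5L, PSP = 5L),
                                     seed = 1L, sd = 1) {
  subjects <- tibble::tibble(
    group = rep(names(n_per_group), times = n_per_group),
    subject = sprintf("S%03d", seq_len(sum(n_per_group)))
  )
  grid <- tidyr::expand_grid(
    subjects,
    segment = c("head", "shoulder", "hip"),
    visual = c("EO", "EC"),
    amplitude = c(0.5, 1),
    frequency_hz = PRTS_ANALYSIS_FREQUENCIES
  )
  grid$gain <- with_seed(seed, stats::rnorm(nrow(grid), 1, sd))
  grid
}
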