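# Frequency-domain estimation of stimulus-to-segment transfer functions:
# block segmentation over stimulus periods, DFT at the excited harmonics,
# cross-spectral sensitivity function (gain/phase) and magnitude-squared
# coherence, band-averaged onto the 11 nominal analysis frequencies.
#
# A ternary m-sequence satisfies s(t + T/2) = -s(t), so the PRTS velocity and
# position waveforms carry energy only at ODD harmonics of the fundamental
# 1/T. Transfer functions are therefore estimated at the excited odd
# harmonics and the spectra averaged within 11 frequency bands whose nominal
# centers are the standard analysis frequencies 0.05-2.2 Hz.

#' Segment trials into stimulus-period blocks
#'
#' Splits each trial's paired (stimulus, response) series into whole stimulus
#' periods, dropping the first period of every trial to eliminate the
#' transient. With the standard protocol (two 60 s trials per condition, 20 s
#' period) this yields four 20 s data blocks.
#'
#' @param trials A list of trials; each a data frame with columns `stimulus`
#'   and `response` sampled at `rate` Hz.
#' @param period_s Stimulus period, seconds (default 20).
#' @param rate Sample rate, Hz (default 100).
#' @param drop_first Number of leading periods discarded per trial (default 1).
#' @return An object of class `sway_blocks`: a tibble with columns `block`,
#'   `sample`, `stimulus`, `response`, with `period_s` and `rate` attributes.
#' @examples
#' d <- prts_design()
#' tr <- build_trial(states_to_position(generate_prts_states(d), d), 3)
#' trial <- data.frame(stimulus = tr$position_deg, response = tr$position_deg)
#' b <- segment_blocks(list(trial, trial))
#' n_blocks(b)  # 4
#' @export
segment_blocks <- function(trials, period_s = 20, rate = 100, drop_first = 1L) {
  if (inherits(trials, "data.frame")) trials <- list(trials)
  n_per <- as.integer(round(period_s * rate))
  pieces <- list()
  for (tr in trials) {
    if (is.null(tr$stimulus) || is.null(tr$response))
      stop("Each trial needs `stimulus` and `response` columns.", call. = FALSE)
    n <- nrow(tr)
    n_cycles <- n %/% n_per
    if (n_cycles < drop_first + 1L)
      stop("Trial too short: ", n, " samples hold ", n_cycles,
           " whole period(s); need at least ", drop_first + 1L, ".",
           call. = FALSE)
    for (k in seq.int(drop_first + 1L, n_cycles)) {
      idx <- ((k - 1L) * n_per + 1L):(k * n_per)
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        sample = seq_len(n_per),
        stimulus = tr$stimulus[idx],
        response = tr$response[idx]
      )
    }
  }
  out <- dplyr::bind_rows(pieces, .id = "block")
  out$block <- as.integer(out$block)
  attr(out, "period_s") <- period_s
  attr(out, "rate") <- rate
  class(out) <- c("sway_blocks", class(out))
  out
}

#' Number of blocks in a block set
#' @param blocks A `sway_blocks` object.
#' @return Integer block count.
#' @export
n_blocks <- function(blocks) {
  length(unique(blocks$block))
}

#' DFT coefficients at requested frequencies
#'
#' Complex DFT coefficients of one data block at the requested frequencies.
#' Each frequency must fall on an integer DFT bin of the block (i.e. be a
#' harmonic of `rate / n`), which holds by construction when blocks are exact
#' stimulus periods — the analysis is then leakage-free with no window. The
#' per-block mean (bin 0) is removed; nonzero bins are unaffected.
#'
#' @param x Numeric vector, one block of samples.
#' @param frequencies Frequencies, Hz.
#' @param rate Sample rate, Hz.
#' @return Complex vector, one coefficient per frequency (normalised by the
#'   block length; an amplitude-A cosine at a bin gives modulus A/2).
#' @export
dft_coefficients <- function(x, frequencies, rate = 100) {
  n <- length(x)
  bins <- frequencies * n / rate
  if (any(abs(bins - round(bins)) > 1e-6))
    stop("Frequencies must fall on integer DFT bins of the block; offending: ",
         paste(frequencies[abs(bins - round(bins)) > 1e-6], collapse = ", "),
         call. = FALSE)
  bins <- as.integer(round(bins))
  if (any(bins < 1L | bins > n %/% 2L))
    stop("Analysis bins must lie in 1..n/2.", call. = FALSE)
  coefs <- stats::fft(x - mean(x)) / n
  coefs[bins + 1L]
}

#' Frequency bands of the PRTS analysis
#'
#' Maps the excited odd harmonics of the stimulus fundamental onto the 11
#' nominal analysis frequencies. Band edges are the geometric midpoints
#' between adjacent nominal centers; the top band extends one half-step in
#' log frequency beyond the last center. Every band contains at least one
#' excited harmonic.
#'
#' @param design A [prts_design()].
#' @param centers Nominal analysis frequencies, Hz.
#' @return A tibble `band`, `center_hz`, `harmonic_hz` with one row per
#'   excited harmonic.
#' @examples
#' prts_band_table(prts_design())
#' @export
prts_band_table <- function(design, centers = PRTS_ANALYSIS_FREQUENCIES) {
  centers <- excited_frequencies(design, centers)
  band_table(1 / design$period_s, centers)
}

band_table <- function(fundamental, centers) {
  edges <- sqrt(centers[-length(centers)] * centers[-1])
  top <- centers[length(centers)]^2 / edges[length(edges)]
  k_max <- floor(top / fundamental + 1e-9)
  k <- seq(1L, k_max, by = 2L)  # excited (odd) harmonics only
  harm <- k * fundamental
  band <- findInterval(harm, edges) + 1L
  tibble::tibble(band = band, center_hz = centers[band], harmonic_hz = harm)
}

# band index of arbitrary frequencies, clamped into 1..11
band_index <- function(f, centers = PRTS_ANALYSIS_FREQUENCIES) {
  edges <- sqrt(centers[-length(centers)] * centers[-1])
  findInterval(abs(f), edges) + 1L
}

#' Estimate the sensitivity (transfer) function from a block set
#'
#' Frequency-response estimation by the indirect approach: at each excited
#' harmonic the cross-spectral density between stimulus and response and the
#' power spectral density of the stimulus are averaged across blocks; the
#' averaged spectra are then pooled within analysis bands and their ratio
#' `H(f) = S_xy(f) / S_xx(f)` gives the sensitivity function at each of the
#' 11 nominal analysis frequencies. Gain is `|H|` (deg response per deg
#' stimulus); phase is `arg(H)` in degrees, unwrapped along ascending
#' frequency and reported with lag negative (anchored into (-360, +90],
#' admitting the small anticipatory lead seen at the lowest frequency).
#' Coherence is attached when two or more blocks are available.
#'
#' With `band_average = FALSE` the estimate is returned at every excited
#' harmonic instead (no pooling), which is the natural resolution for
#' estimator identities such as pure time shifts.
#'
#' @param blocks A `sway_blocks` object from [segment_blocks()].
#' @param frequencies Nominal analysis frequencies, Hz (default: the standard
#'   11-frequency set).
#' @param band_average Pool excited harmonics within analysis bands (default
#'   `TRUE`).
#' @param coherence_type `"squared"` for magnitude-squared coherence (default)
#'   or `"magnitude"` for its square root.
#' @return A tibble of class `tf_estimate`: `frequency_hz`, `gain`,
#'   `phase_deg`, `coherence`, `n_blocks` (plus `n_harmonics` when band
#'   averaging).
#' @examples
#' d <- prts_design()
#' tr <- build_trial(states_to_position(generate_prts_states(d), d), 3)
#' trial <- data.frame(stimulus = tr$position_deg, response = tr$position_deg)
#' estimate_sensitivity(segment_blocks(list(trial, trial)))
#' @export
estimate_sensitivity <- function(blocks,
                                 frequencies = PRTS_ANALYSIS_FREQUENCIES,
                                 band_average = TRUE,
                                 coherence_type = c("squared", "magnitude")) {
  coherence_type <- match.arg(coherence_type)
  stopifnot(inherits(blocks, "sway_blocks"))
  rate <- attr(blocks, "rate")
  bt <- band_table_for(blocks, frequencies, band_average)
  spectra <- block_spectra(blocks, bt$harmonic_hz, rate)
  nb <- length(spectra)

  s_xx <- Reduce(`+`, lapply(spectra, function(s) Mod(s$x)^2)) / nb
  s_xy <- Reduce(`+`, lapply(spectra, function(s) Conj(s$x) * s$y)) / nb
  if (any(s_xx <= 0))
    stop("Stimulus has no energy at analysis frequencies: ",
         paste(bt$harmonic_hz[s_xx <= 0], collapse = ", "), call. = FALSE)

  g <- factor(bt$band, levels = sort(unique(bt$band)))
  pool <- function(v) as.vector(tapply(v, g, sum))
  h <- complex(real = pool(Re(s_xy)), imaginary = pool(Im(s_xy))) / pool(s_xx)
  phase <- unwrap_phase_deg(Arg(h) * 180 / pi)

  out <- tibble::tibble(
    frequency_hz = if (band_average) frequencies else bt$harmonic_hz,
    gain = Mod(h),
    phase_deg = phase,
    coherence = if (nb >= 2L)
      coherence_from_spectra(spectra, g, coherence_type) else NA_real_,
    n_blocks = nb,
    n_harmonics = as.vector(table(g))
  )
  if (nb < 2L)
    warning("Coherence undefined with a single block; reported as NA.",
            call. = FALSE)
  class(out) <- c("tf_estimate", class(out))
  out
}

#' Estimate stimulus-response coherence from a block set
#'
#' Magnitude-squared coherence at each analysis frequency: the squared
#' modulus of the cross-spectrum summed over blocks (and over the excited
#' harmonics pooled in each analysis band) divided by the product of the
#' summed stimulus and response power spectra,
#' `gamma^2(f) = |sum S_xy|^2 / (sum S_xx * sum S_yy)`.
#' A value of 1 indicates a perfectly reproducible linear stimulus-response
#' relation; values below 1 arise from remnant noise or nonlinearity. By
#' Cauchy-Schwarz the estimate always lies in [0, 1]. With a single block and
#' a single pooled harmonic the estimator is degenerate (identically 1), so
#' fewer than 2 blocks yields `NA` with a warning.
#'
#' @inheritParams estimate_sensitivity
#' @param type `"squared"` (default) or `"magnitude"`.
#' @return A tibble `frequency_hz`, `coherence`, `n_blocks`.
#' @export
estimate_coherence <- function(blocks,
                               frequencies = PRTS_ANALYSIS_FREQUENCIES,
                               band_average = TRUE,
                               type = c("squared", "magnitude")) {
  type <- match.arg(type)
  stopifnot(inherits(blocks, "sway_blocks"))
  bt <- band_table_for(blocks, frequencies, band_average)
  spectra <- block_spectra(blocks, bt$harmonic_hz, attr(blocks, "rate"))
  g <- factor(bt$band, levels = sort(unique(bt$band)))
  if (length(spectra) < 2L) {
    warning("Coherence requires at least 2 blocks; returning NA.",
            call. = FALSE)
    coh <- rep(NA_real_, nlevels(g))
  } else {
    coh <- coherence_from_spectra(spectra, g, type)
  }
  tibble::tibble(
    frequency_hz = if (band_average) frequencies else bt$harmonic_hz,
    coherence = coh,
    n_blocks = length(spectra)
  )
}

# harmonics and band assignment used by the estimators
band_table_for <- function(blocks, frequencies, band_average) {
  period_s <- attr(blocks, "period_s")
  if (band_average) {
    band_table(1 / period_s, frequencies)
  } else {
    fundamental <- 1 / period_s
    k <- round(frequencies / fundamental)
    if (any(abs(frequencies / fundamental - k) > 1e-9))
      stop("Frequencies must be harmonics of the block fundamental.",
           call. = FALSE)
    tibble::tibble(band = seq_along(frequencies), center_hz = frequencies,
                   harmonic_hz = frequencies)
  }
}

block_spectra <- function(blocks, frequencies, rate) {
  lapply(split(blocks[c("stimulus", "response")], blocks$block), function(b) {
    list(x = dft_coefficients(b$stimulus, frequencies, rate),
         y = dft_coefficients(b$response, frequencies, rate))
  })
}

coherence_from_spectra <- function(spectra, g, type) {
  s_xy <- Reduce(`+`, lapply(spectra, function(s) Conj(s$x) * s$y))
  s_xx <- Reduce(`+`, lapply(spectra, function(s) Mod(s$x)^2))
  s_yy <- Reduce(`+`, lapply(spectra, function(s) Mod(s$y)^2))
  pool <- function(v) as.vector(tapply(v, g, sum))
  num <- Mod(complex(real = pool(Re(s_xy)), imaginary = pool(Im(s_xy))))^2
  gamma2 <- num / (pool(s_xx) * pool(s_yy))
  gamma2 <- pmin(pmax(gamma2, 0), 1)  # guard rounding at the CS bound
  if (type == "magnitude") sqrt(gamma2) else gamma2
}

# Unwrap a phase sequence (degrees) along ascending frequency, then anchor it
# into (-360, +90]: lags negative, small anticipatory leads allowed.
unwrap_phase_deg <- function(phase) {
  if (length(phase) > 1L) {
    d <- diff(phase)
    jumps <- cumsum(c(0, -360 * (d > 180) + 360 * (d < -180)))
    phase <- phase + jumps
  }
  shift <- 0
  while (phase[1] + shift > 90) shift <- shift - 360
  while (phase[1] + shift <= -360) shift <- shift + 360
  phase + shift
}
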