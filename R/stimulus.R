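# PRTS stimulus design: maximal-length ternary sequences over GF(3) and the
# derived platform tilt waveforms.

#' Create a PRTS stimulus design
#'
#' Specifies a pseudorandom ternary sequence (PRTS) platform-tilt stimulus: a
#' maximal-length sequence over GF(3) generated by an `n_stages`-stage linear
#' feedback shift register, held for `state_increment` seconds per state,
#' driving platform angular velocity. Its integral is the tilt-angle
#' disturbance. The default design (4 stages, 0.25 s increment) gives an
#' 80-state sequence and a 20 s period with energy concentrated at harmonics
#' of 0.05 Hz.
#'
#' @param n_stages Shift-register length (sequence length is `3^n_stages - 1`).
#' @param state_increment Hold time per ternary state, seconds.
#' @param sample_rate Output sample rate, Hz. `state_increment * sample_rate`
#'   must be an integer.
#' @param peak_amplitude Peak platform tilt, degrees. Interpreted according to
#'   `amplitude_mode`.
#' @param amplitude_mode `"peak"` (max absolute tilt equals `peak_amplitude`,
#'   the default) or `"peak_to_peak"` (total excursion equals it).
#' @param feedback_taps Integer vector of GF(3) feedback coefficients, length
#'   `n_stages`. The default taps for 4 stages give the full 80-state period;
#'   taps are validated for maximality at construction.
#' @param initial_register Ternary digits seeding the register; must not be
#'   all zero.
#'
#' @return An object of class `prts_design` (a list with the above fields plus
#'   derived constants `n_states`, `period_s`, `samples_per_state`).
#' @examples
#' d <- prts_design()
#' d$n_states   # 80
#' d$period_s   # 20
#' @export
prts_design <- function(n_stages = 4L,
                        state_increment = 0.25,
                        sample_rate = 100,
                        peak_amplitude = 0.5,
                        amplitude_mode = c("peak", "peak_to_peak"),
                        feedback_taps = NULL,
                        initial_register = NULL) {
  amplitude_mode <- match.arg(amplitude_mode)
  n_stages <- as.integer(n_stages)
  if (n_stages < 2L) stop("`n_stages` must be at least 2.", call. = FALSE)
  if (state_increment <= 0) stop("`state_increment` must be positive.", call. = FALSE)
  sps <- state_increment * sample_rate
  if (abs(sps - round(sps)) > 1e-9)
    stop("`state_increment * sample_rate` must be an integer number of samples.",
         call. = FALSE)
  if (peak_amplitude <= 0) stop("`peak_amplitude` must be positive.", call. = FALSE)

  if (is.null(feedback_taps)) {
    if (n_stages == 4L) {
      feedback_taps <- c(1L, 0L, 0L, 1L)
    } else {
      stop("No default `feedback_taps` for n_stages = ", n_stages,
           "; supply taps of a primitive GF(3) polynomial.", call. = FALSE)
    }
  }
  feedback_taps <- as.integer(feedback_taps) %% 3L
  if (length(feedback_taps) != n_stages)
    stop("`feedback_taps` must have length `n_stages`.", call. = FALSE)
  if (is.null(initial_register)) initial_register <- c(1L, rep(0L, n_stages - 1L))
  initial_register <- as.integer(initial_register) %% 3L
  if (length(initial_register) != n_stages)
    stop("`initial_register` must have length `n_stages`.", call. = FALSE)
  if (all(initial_register == 0L))
    stop("`initial_register` must not be all zero (the zero state is absorbing).",
         call. = FALSE)

  design <- structure(
    list(
      n_stages = n_stages,
      state_increment = state_increment,
      sample_rate = sample_rate,
      peak_amplitude = peak_amplitude,
      amplitude_mode = amplitude_mode,
      feedback_taps = feedback_taps,
      initial_register = initial_register,
      n_states = as.integer(3^n_stages - 1),
      samples_per_state = as.integer(round(sps)),
      period_s = (3L^n_stages - 1L) * state_increment
    ),
    class = "prts_design"
  )
  # maximality check: the register must cycle through all 3^n - 1 nonzero
  # states before returning to the seed
  validate_prts_taps(design)
  design
}

#' @export
print.prts_design <- function(x, ...) {
  cat("<prts_design>\n")
  cat("  stages: ", x$n_stages, " (", x$n_states, " states x ",
      x$state_increment, " s = ", x$period_s, " s period)\n", sep = "")
  cat("  sample rate: ", x$sample_rate, " Hz; peak amplitude: ",
      x$peak_amplitude, " deg (", x$amplitude_mode, ")\n", sep = "")
  cat("  taps: (", paste(x$feedback_taps, collapse = ", "), ")  seed: (",
      paste(x$initial_register, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

prts_register_step <- function(register, taps) {
  c(sum(taps * register) %% 3L, register[-length(register)])
}

validate_prts_taps <- function(design) {
  r0 <- design$initial_register
  r <- r0
  n_max <- 3L^design$n_stages
  for (k in seq_len(n_max)) {
    r <- prts_register_step(r, design$feedback_taps)
    if (all(r == r0)) {
      if (k != design$n_states)
        stop("`feedback_taps` do not generate a maximal-length sequence ",
             "(period ", k, ", expected ", design$n_states, ").", call. = FALSE)
      return(invisible(TRUE))
    }
  }
  stop("`feedback_taps` do not return the register to its seed; ",
       "not a maximal-length sequence.", call. = FALSE)
}

#' Generate the ternary state sequence of a PRTS design
#'
#' Runs the GF(3) linear feedback shift register for one full period and maps
#' the register output symbols \{0, 1, 2\} to the ternary velocity commands
#' \{0, +1, -1\}.
#'
#' @param design A [prts_design()].
#' @return Integer vector of length `design$n_states` over \{0, +1, -1\}.
#' @examples
#' s <- generate_prts_states(prts_design())
#' length(s)  # 80
#' table(s)   # 26 zeros, 27 each of +1 and -1
#' @export
generate_prts_states <- function(design) {
  stopifnot(inherits(design, "prts_design"))
  r <- design$initial_register
  out <- integer(design$n_states)
  for (k in seq_len(design$n_states)) {
    out[k] <- r[design$n_stages]
    r <- prts_register_step(r, design$feedback_taps)
  }
  # {0,1,2} -> {0,+1,-1}
  ifelse(out == 2L, -1L, out)
}

#' Build the velocity and position waveforms of a PRTS stimulus
#'
#' Expands the ternary state sequence into a zero-order-hold angular velocity
#' waveform, integrates it (rectangular rule, consistent with the piecewise
#' constant velocity command) into an angular position waveform, and rescales
#' the position so its amplitude matches the design. Because a maximal-length
#' ternary sequence is balanced (equal counts of +1 and -1), the velocity
#' integrates to zero over one period and the position is periodic.
#'
#' @param states Ternary state sequence from [generate_prts_states()], over
#'   \{0, +1, -1\}.
#' @param design The [prts_design()] the states were generated from.
#' @return A tibble with one row per sample over one period: `time_s`,
#'   `velocity_deg_s`, `position_deg`, carrying the design and the excited
#'   frequencies as attributes (class `prts_waveforms`).
#' @examples
#' d <- prts_design()
#' w <- states_to_position(generate_prts_states(d), d)
#' max(abs(w$position_deg))  # 0.5
#' @export
states_to_position <- function(states, design) {
  stopifnot(inherits(design, "prts_design"))
  if (length(states) != design$n_states)
    stop("`states` must have length ", design$n_states, ".", call. = FALSE)
  if (!all(states %in% c(-1L, 0L, 1L)))
    stop("`states` must take values in {-1, 0, +1}.", call. = FALSE)

  dt <- 1 / design$sample_rate
  velocity <- rep(as.numeric(states), each = design$samples_per_state)
  # left-Riemann integral: position[1] = 0 and, by symbol balance, the value
  # after a full cycle returns to 0
  position <- dt * (cumsum(velocity) - velocity)
  peak <- max(abs(position))
  if (peak > 0) {
    scale <- switch(design$amplitude_mode,
                    peak = design$peak_amplitude / peak,
                    peak_to_peak = design$peak_amplitude / diff(range(position)))
    velocity <- velocity * scale
    position <- position * scale
  }
  n <- length(position)
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1L) * dt,
    velocity_deg_s = velocity,
    position_deg = position
  )
  attr(out, "design") <- design
  attr(out, "excited_frequencies") <- excited_frequencies(design)
  class(out) <- c("prts_waveforms", class(out))
  out
}

#' Repeat a stimulus period into a trial
#'
#' Concatenates `n_cycles` identical periods of the position waveform into the
#' disturbance delivered during one trial (three 20 s cycles give the 60 s
#' trial of the standard protocol).
#'
#' @param waveforms A `prts_waveforms` tibble from [states_to_position()].
#' @param n_cycles Number of stimulus cycles (>= 1).
#' @return A tibble with `time_s`, `position_deg` spanning
#'   `n_cycles * period_s` seconds, with the design attributes retained.
#' @examples
#' d <- prts_design()
#' trial <- build_trial(states_to_position(generate_prts_states(d), d), 3)
#' nrow(trial)  # 6000 samples = 60 s at 100 Hz
#' @export
build_trial <- function(waveforms, n_cycles = 3L) {
  stopifnot(inherits(waveforms, "prts_waveforms"))
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L)
    stop("`n_cycles` must be a positive integer.", call. = FALSE)
  design <- attr(waveforms, "design")
  n <- nrow(waveforms)
  pos <- rep(waveforms$position_deg, times = n_cycles)
  out <- tibble::tibble(
    time_s = (seq_along(pos) - 1L) / design$sample_rate,
    position_deg = pos
  )
  attr(out, "design") <- design
  attr(out, "excited_frequencies") <- attr(waveforms, "excited_frequencies")
  attr(out, "n_cycles") <- n_cycles
  class(out) <- c("prts_trial", class(out))
  out
}

# The analysis set: harmonics of the 0.05 Hz fundamental at which the PRTS
# concentrates energy and the transfer function is evaluated.
PRTS_ANALYSIS_FREQUENCIES <- c(0.05, 0.15, 0.3, 0.4, 0.55, 0.7, 0.9, 1.1,
                               1.35, 1.75, 2.2)

#' Excited analysis frequencies of a PRTS design
#'
#' Returns the fixed set of analysis frequencies at which transfer functions
#' are evaluated. Every frequency must be an integer harmonic of the stimulus
#' fundamental `1 / period_s` (0.05 Hz for the default design); a frequency
#' off the harmonic grid is an error because the corresponding DFT bin would
#' not be leakage-free.
#'
#' @param design A [prts_design()].
#' @param frequencies Candidate analysis frequencies, Hz. Defaults to the
#'   standard 11-frequency set 0.05-2.2 Hz.
#' @return Numeric vector of analysis frequencies, Hz.
#' @examples
#' excited_frequencies(prts_design())  # 11 harmonics of 0.05 Hz
#' @export
excited_frequencies <- function(design, frequencies = PRTS_ANALYSIS_FREQUENCIES) {
  stopifnot(inherits(design, "prts_design"))
  fundamental <- 1 / design$period_s
  harmonics <- frequencies / fundamental
  if (any(abs(harmonics - round(harmonics)) > 1e-9))
    stop("Analysis frequencies must be integer multiples of the fundamental ",
         signif(fundamental, 6), " Hz; offending: ",
         paste(frequencies[abs(harmonics - round(harmonics)) > 1e-9],
               collapse = ", "), call. = FALSE)
  frequencies
}

#' Export a stimulus trial as delimited text
#'
#' Writes a two-column tab-separated file (`time_s`, `platform_angle_deg`) and
#' an optional JSON sidecar capturing the full design configuration.
#'
#' @param trial A `prts_trial` tibble from [build_trial()].
#' @param path Output path for the waveform table.
#' @param config_path Optional path for the JSON design sidecar.
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(trial, path, config_path = NULL) {
  stopifnot(inherits(trial, "prts_trial"))
  readr::write_tsv(
    tibble::tibble(time_s = trial$time_s, platform_angle_deg = trial$position_deg),
    path
  )
  if (!is.null(config_path)) {
    design <- attr(trial, "design")
    cfg <- c(design[c("n_stages", "state_increment", "sample_rate",
                      "peak_amplitude", "amplitude_mode", "feedback_taps",
                      "initial_register")],
             list(n_cycles = attr(trial, "n_cycles")))
    jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
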