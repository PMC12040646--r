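# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transfer-function estimate
#'
#' @param x A `tf_estimate` from [estimate_sensitivity()].
#' @param ... Unused.
#' @return A tibble with one row per analysis frequency: `frequency_hz`,
#'   `gain`, `phase_deg`, `coherence`, `n_blocks`.
#' @export
tidy.tf_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a transfer-function estimate
#'
#' @param x A `tf_estimate`.
#' @param ... Unused.
#' @return A tibble with `n_frequencies`, `n_blocks`, `mean_gain`,
#'   `max_gain`, `mean_coherence`, `min_phase_deg`.
#' @export
glance.tf_estimate <- function(x, ...) {
  tibble::tibble(
    n_frequencies = nrow(x),
    n_blocks = x$n_blocks[1],
    mean_gain = mean(x$gain),
    max_gain = max(x$gain),
    mean_coherence = mean(x$coherence),
    min_phase_deg = min(x$phase_deg)
  )
}

#' Tidy an ANOVA effect table
#'
#' @param x A `sway_anova` from [factorial_anova()].
#' @param ... Unused.
#' @return The effect table as a plain tibble.
#' @export
tidy.sway_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of an ANOVA effect table
#'
#' @param x A `sway_anova`.
#' @param ... Unused.
#' @return A tibble with the effect count and the number significant at 0.05.
#' @export
glance.sway_anova <- function(x, ...) {
  tibble::tibble(
    n_effects = nrow(x),
    n_significant = sum(x$p.value < 0.05, na.rm = TRUE),
    min_p = min(x$p.value, na.rm = TRUE)
  )
}
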