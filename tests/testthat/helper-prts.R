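# Shared fixtures, built once per test run.

default_design <- prts_design()
default_waveforms <- states_to_position(generate_prts_states(default_design),
                                        default_design)
default_trial <- build_trial(default_waveforms, 3)

# a ground-truth profile with a constant transfer function H at every
# analysis frequency (bypasses the group presets)
constant_profile <- function(h, noise_sd = 0) {
  p <- ground_truth_profile("head", "CTR", noise_sd = noise_sd)
  p$gain <- rep(Mod(h), length(p$frequency_hz))
  p$phase_deg <- rep(Arg(h) * 180 / pi, length(p$frequency_hz))
  p$H <- rep(h, length(p$frequency_hz))
  p
}

# paired-trial block set from a response vector (two identical trials ->
# four blocks under the standard protocol)
blocks_from_response <- function(response, stimulus = default_trial$position_deg,
                                 n_trials = 2) {
  trial <- data.frame(stimulus = stimulus, response = response)
  segment_blocks(rep(list(trial), n_trials))
}
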