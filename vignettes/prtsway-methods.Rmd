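---
title: "Methods: PRTS posturography analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRTS posturography analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prtsway)
```

`prtsway` implements a frequency-domain pipeline for dynamic posturography
with pseudorandom support-surface tilts. This vignette explains the model
and the numerical choices behind each stage, what the synthetic-data
generator does and does not emulate, and the known limitations. It states
no empirical result beyond what the package's tests and acceptance script
compute.

## The stimulus: a ternary maximal-length sequence

A 4-stage linear feedback shift register over GF(3) produces a
maximal-length sequence of 3^4 − 1 = 80 ternary states. Held for 0.25 s
each, the symbols (mapped {0, 1, 2} → {0, +1, −1}) command platform
angular velocity; rectangular integration — consistent with the piecewise
constant command — yields the 20 s periodic tilt-angle disturbance, which
`build_trial()` repeats three times into a 60 s trial. Because the
maximal-length sequence is balanced (27 of each nonzero symbol, 26 zeros),
the velocity integrates to zero over a period and the position waveform is
drift-free.

The recurrence is `s[t] = s[t−1] + s[t−4] (mod 3)`, i.e. the feedback taps
(1, 0, 0, 1); eight tap sets are maximal for four stages, and construction
verifies maximality by running the register through a full period. The
default seed register is (1, 0, 0, 0). Both are configurable; the spectral
properties below hold for any maximal choice.

**Amplitude convention.** Peak tilt amplitudes of 0.5° and 1° are
interpreted as the maximum absolute tilt (`amplitude_mode = "peak"`), with
`"peak_to_peak"` available as an option; device conventions differ and the
two readings disagree by roughly a factor of two, so the choice is explicit
in the design object and recorded in exported configs.

**Excited frequencies and analysis bands.** Any ternary m-sequence
satisfies s(t + T/2) = −s(t), so its waveforms carry energy only at *odd*
harmonics of the fundamental 1/T = 0.05 Hz; even harmonics are identically
zero. The conventional 11 analysis frequencies (0.05–2.2 Hz) include even
harmonics, so they are treated as *nominal band centers*: estimates are
formed at every excited odd harmonic up to ~2.45 Hz and pooled within 11
bands whose edges are the geometric midpoints between adjacent centers.
Each band contains 1–5 excited harmonics; `prts_band_table()` exposes the
assignment, and `band_average = FALSE` returns harmonic-resolution
estimates (the natural scale for estimator identities such as pure time
shifts).

## Kinematics: from markers to segment angles

Ultrasound markers arrive at a dynamic 80–200 Hz rate. `resample_uniform()`
linearly interpolates onto an exact 100 Hz grid within the recorded span
(no extrapolation); gaps longer than 0.25 s are bridged but flagged
`valid = FALSE` so affected blocks can be excluded. Left/right marker pairs
at head and shoulder level are averaged into midsagittal tracks.

Segment angles use the position-based definition: the sway angle about the
ankle axis, `angle = atan2(y − y_ref, h)`, where `y` is the marker's
anteroposterior excursion, `y_ref` its quiet-stance mean (by protocol, the
30 s pre-stimulus epoch; configurable), and `h` the marker height above the
ankle axis from the subject's anthropometrics. This matches the
angle-in-space framing of the transfer-function analysis; an
orientation-based alternative (marker-pair vector vs. vertical) would
capture intersegmental articulation instead and is deliberately out of
scope of the default path. In the small-angle regime of these experiments
(|angle| < 15°) the forward model `y = y_ref + h·tan(angle)` inverts
exactly, which the round-trip tests exploit.

The head-position distribution histograms the central head marker's
anteroposterior excursion over ±10 cm in 1 cm bins, normalised to unit
mass, with out-of-range samples clipped into the edge bins. (The bin unit
is a design choice: positions are measured in cm, so a 1 cm bin over the
±10 cm support is used.)

## Spectral estimation

Blocks are exact stimulus periods, so the analysis bins are leakage-free
with a rectangular window by construction; only the per-block mean is
removed (nonzero bins are unaffected, and slow trends are handled by
discarding each trial's first cycle as a transient). Averaging happens at
the power-spectral level: S_xy and S_xx are averaged across blocks before
the ratio H = S_xy/S_xx is formed. For a periodic stimulus this yields the
same gain and phase as averaging Fourier coefficients first, but it is the
order that makes coherence meaningful — coefficient-first averaging would
force coherence to 1 identically, incompatible with any coherence below 1.
Coherence defaults to the magnitude-squared form γ², with |γ| selectable
(`coherence_type = "magnitude"`); γ² is the quantity with the direct
SNR/(1 + SNR) interpretation. With a single block the coherence estimator
is degenerate and is reported as missing rather than silently 1.

Phase is unwrapped along ascending frequency and anchored into
(−360°, +90°]: lags are negative, and the window admits the small
anticipatory lead that appears at the lowest frequency. Unwrapping assumes
the true phase changes by less than 180° between adjacent analysis
frequencies, which holds for physiological delays (≲1 s) across this band.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuned per run.

**Cohort and design.** 19 control, 11 IPD and 17 PSP synthetic subjects;
per subject, eyes open/closed × 0.5°/1° tilt, each condition twice — eight
60 s trials — with transfer functions for head, shoulder and hip.

**Presets.** Group × segment gain profiles at the 11 analysis frequencies
encode the qualitative structure of the clinical findings — head ≥
shoulder ≥ hip within each group, PSP > IPD > CTR at every frequency, a
PSP head-gain peak in the 0.15–0.4 Hz mid-band, low-pass roll-off above
~1 Hz — without digitising any published figure. Mid-band head-gain ratios
are constructed exactly: PSP/CTR = 5 and PSP/IPD = 2, so ratio recovery has
a known truth. Phase presets lead slightly (+8° intercept) and lag
linearly with frequency, steeper for higher segments. Condition effects
are group-independent multipliers (eyes closed ×1.12; 0.5° ×1.15 relative
to 1°) so that group ratios pooled across conditions remain at their
constructed values; consequently the synthetic data carry no
group×condition interactions, which is a deliberate simplification.

**Subject heterogeneity** is a log-normal multiplicative gain perturbation
(σ = 0.2) per subject × segment, keeping gains positive. With ~17 subjects
per group the group-mean ratio then varies by roughly ±7% (1 SE) around
the constructed value, which is why ratio-recovery checks use a 15% band.

**Remnant noise** defaults to pink (1/f amplitude shaping), reflecting the
low-frequency dominance of spontaneous sway, at sd 0.025° per trial. The
level was fixed once against the generator's own stated recovery contract
— median absolute gain error below 10% and median phase error below 10° at
every analysis frequency on the default cohort — which it meets with
margin while still producing the characteristic coherence decline from
~1.0 at 0.05 Hz to ~0.5–0.6 at 2.2 Hz as remnant power overtakes the
stimulus's shrinking high-frequency energy. Real recordings are less
well-behaved: nonlinearity, nonstationarity (fatigue, habituation),
marker dropout bursts and inter-trial strategy changes all depress
coherence in ways the generator does not emulate, so passing recovery
tests here demonstrates estimator correctness, not field performance.

**Synthesis** is exact in the frequency domain: each spectral bin of the
stimulus is multiplied by the H of the analysis band it falls in
(band-constant application), so a noiseless synthesis followed by
estimation returns the profile to floating-point accuracy — the basis of
the round-trip tests. Marker emission inverts the kinematics chain with
the same rigid-rod geometry (9 markers, left/right pairs ±4 cm laterally)
and draws irregular timestamps uniformly in [1/200, 1/80] s.

**The feedback simulator** is a separate, dynamical route to synthetic
sway: a single-link inverted pendulum (mass 75 kg, CoM 0.95 m, rod-like
inertia) stabilised by a delayed proportional–derivative controller acting
on a weighted mix of body-to-surface (proprioceptive, weight w) and
body-to-space (graviceptive, 1 − w) error. It is a deliberately simple
stand-in for the multisegment feedback models of the posturography
literature, not a reproduction of any published parameterisation. With
w = 1 the body tracks the platform at low frequency (egocentric strategy,
gain → Kp/(Kp − mgh) ≈ 1.14 at the defaults); with w = 0 it stays earth
vertical (gain → 0). Defaults are Kp = 8·mgh, Kd = 0.35·Kp and a lumped
50 ms delay: a pure delayed-PD loop cannot combine near-unity
low-frequency tracking (which needs Kp ≫ mgh) with stability at
~100–150 ms physiological delays — the phase margin goes negative — so the
lumped delay is kept short and should be read as an effective value after
neural prediction. Stability is checked at construction by simulating the
unforced response to a 1° lean for 10 s and requiring decay; the
closed-form frequency response `feedback_frequency_response()` provides
the analytic reference, and the time-domain integrator (semi-implicit
Euler at 8 substeps per 100 Hz sample, one warm-up stimulus period
discarded) agrees with it to ~1–3% across the band.

## Group statistics

Cell summaries are t-based means with 95% confidence half-widths per
group × segment × visual × amplitude × frequency cell — the whisker
convention appropriate for small groups; a bootstrap adds little at n ≤ 19
and would introduce another randomness source. Gain-ratio contrasts
band-average per-subject gains (default 0.15–0.4 Hz, the mid-band where
the PSP elevation is constructed) before taking the ratio of group means.

The factorial analysis is a two-stratum repeated-measures ANOVA: group
between subjects, segment/visual/amplitude/frequency within, subject as
the error stratum, frequency entering as a categorical factor (11 levels)
to match per-frequency plotting. Tested interactions default to the
group-involving set plus segment:visual (included so the three-way
group:segment:visual term keeps its factorial degrees of freedom). The
layout must be balanced — synthetic cohorts are by construction; for real,
unbalanced data the intended route is per-subject cell means first.
Pairwise group contrasts on band-averaged gain use Welch t-tests with
Bonferroni adjustment over the contrast family. Exact replication of any
particular published F statistic is not a goal (the underlying patient
data are not available); what the tests pin down instead is calibration —
near-nominal type-I error under a null cohort — and effect direction on
the constructed presets.

## Problem sizes and determinism

The validation suite runs at desk scale by design: full default cohorts
(47 subjects × 8 trials × 3 segments) for recovery checks, 200-replicate
Monte-Carlo runs for the coherence–SNR law (40 blocks per replicate) and
ANOVA calibration (12-subject null cohorts), all completing in a few
minutes on one CPU. Every random draw — subject multipliers, remnant
noise, timestamps — derives from explicit seeds threaded through
`generate_cohort()`, `synthesize_response()` and `emit_marker_files()`;
identical seeds give bit-identical outputs, which the determinism tests
assert.

## Known limitations

* Single-pivot geometry: all segment angles share the ankle pivot; the
  model has no articulated neck or hip joint, so intersegmental dynamics
  (e.g. head-on-trunk resonance) are outside the generator's vocabulary.
* The independent-channel feedback simulator is single-link and linear;
  it cannot produce the mid-band gain peak of the PSP preset, which is why
  presets and simulator are separate synthesis routes.
* Band-averaged phase is a power-weighted circular mean within each band;
  for steep phase slopes (long delays) it reflects the band's weighted
  mean frequency rather than the nominal center.
* Knee markers are ingested and emitted but not analysed, mirroring the
  upstream protocol's reported scope; center-of-pressure processing is out
  of scope.
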