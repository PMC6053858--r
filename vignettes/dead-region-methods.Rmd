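---
title: "Model and methods: adaptive estimation of a dead-region edge frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: adaptive estimation of a dead-region edge frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deadregion)
```

## The problem

A basal cochlear dead region (DR) is a stretch of the cochlea, extending
upward from an edge characteristic frequency f_e, where inner hair cells
or neurons no longer function. Tones whose frequencies fall inside the DR
are heard, if at all, through off-place listening at the functioning edge.
Knowing f_e matters for hearing-aid fitting: amplifying well above the
edge (beyond roughly 1.7 f_e) does not help. The classical behavioural
estimate of f_e is the tip of a psychophysical tuning curve (PTC) — the
masker level just masking a fixed probe tone, as a function of masker
frequency — but measuring a whole PTC is slow.

This package estimates f_e without tracing the PTC. A hearing model
predicts, for any masker, the probability that a listener with candidate
parameters (f_e, OHCL(f_e)) reports hearing the probe; a Bayesian grid
posterior over those two parameters is updated after every yes/no trial;
and each trial's masker is chosen to be maximally informative. In
simulation the estimate typically stabilises within about 0.1–0.2 Cams of
the true edge well before trial 50 of a 100-trial run.

## Frequency scale

All frequency handling uses the ERB_N-number (Cam) scale,
Cam(F) = 21.4 log10(4.37 F + 1) with F in kHz, and
ERB_N(F) = 24.7 (4.37 F + 1) Hz. One Cam step spans one normal auditory
filter bandwidth, which makes constant-Cam grids perceptually uniform.
Audiograms are interpolated linearly in (Cam, dB HL) coordinates, the
same plane the rest of the engine works on; this also makes the
screening frequencies f_65 ≤ f_70 ≤ f_75 stable for monotone losses.

## Excitation model

Detection is evaluated at a single place: the auditory filter centred on
the candidate edge f_e. The probe always lies above f_e, so its maximum
usable excitation occurs at the edge, and outer-hair-cell loss only needs
to be known there. The filter is a rounded-exponential (roex) weighting
W(g) = (1 + p|g|) e^(−p|g|), g = (f − cf)/cf, with:

* upper skirt fixed at the normal sharpness p51 = 4 cf / ERB_N(cf);
* lower skirt p_lower = p51 · max(0.2, 1 − OHCL/65) − 0.35 (p51/p51_1kHz)
  · (L − 51) for input levels L above 51 dB, floored at 0.2 p51.

These coefficients give the qualitative behaviour the procedure relies
on — tuning broadens with level and with OHCL, and PTCs flatten as OHCL
grows — while keeping excitation levels on the dB HL scale (an
on-frequency tone excites at exactly its own level), so they are directly
comparable with audiometric thresholds. The level that sets the
level-dependent slope is the masker's overall level, as the dominant
component of the stimulus; the probe, at 10 dB SL, contributes little to
the context level, and the choice only affects the lower skirt.

The masker is a flat-spectrum noise band of width max(ERB_N(f_mask),
200 Hz). Its excitation is the band average of W, computed with the exact
antiderivative of (1 + u)e^(−u) (namely −(2 + u)e^(−u)) split at the
filter centre; tests verify this closed form against adaptive numerical
quadrature. Bands that would reach below 20 Hz are truncated there and
the average renormalised over the remaining width. A broadband
threshold-equalizing noise (TEN) background of 35 dB HL/ERB_N — present
in the protocol to mask distortion products — is added in intensity; a
broadband TEN specified in level-per-ERB_N excites a normal filter at
exactly its nominal level, and the package generalises this with a
locally-flat spectrum-level approximation, so the background only
matters at very low masker levels.

## Detection likelihood

With E_sig and E_noise the excitations of probe and masker at f_e, and
HL_total(f_e) the audiometric threshold there, the hit probability is

p(yes) = λ + (1 − 2λ) Φ((E_sig − max(E_noise, HL_total(f_e))) / σ)

with slope σ = 3 dB and lapse rate λ = 0.01 by default, so p spans
[0.01, 0.99] and is exactly 0.5 when the excitations balance. The max(·)
substitution makes the threshold in quiet limit audibility. A 3-dB slope
is a reasonable figure for tone-in-noise detection; assuming a slope
steeper than the listener's true one makes the procedure overconfident,
a shallower one makes it waste trials.

## Prior, posterior and updates

The posterior lives on a grid: f_e bins of 0.1 Cam spanning the 8 Cams
below the probe frequency, and OHCL bins of 2.5 dB over 0–65 dB. The
0.1-Cam bin width matches the resolution at which estimates are reported;
2.5-dB OHCL spacing (27 bins) keeps the grid a few thousand cells, small
enough to precompute every cell × candidate-stimulus excitation
difference once per session. The prior is uniform over admissible cells,
excluding: cells with f_e at or above the probe (the edge is known to lie
below it), cells with OHCL > HL_total(f_e), and cells under which the
10-dB-SL probe would be inaudible in quiet — the protocol has already
established it is audible. Updates multiply each cell by the likelihood
of the observed response and renormalise; accumulation is done in log
space because a hundred factors as small as 0.01 underflow linear
arithmetic. Catch trials carry no masking-model likelihood and leave the
posterior untouched; they feed only the false-alarm diagnostic. The
reported estimate is the MAP of the f_e marginal, ties broken toward the
lower bin.

## Stimulus selection

Candidates form a lattice of 0.25-Cam masker frequencies over the 8 Cams
up to the probe, crossed with 20–90 dB HL levels in 2-dB steps (the
lattice is a package choice; 90 dB HL caps presentation levels at a
comfortable-safe value, and the lattice size keeps per-trial evaluation
to one matrix product). Each candidate is scored by the mutual
information between the next response and the parameters — binary
predictive entropy minus expected conditional entropy, at most 1 bit —
and the next stimulus is *sampled* with probability proportional to that
score times a Gaussian weight (sd 1.5 Cams) in Cam distance from the
current f_e estimate. Sampling rather than maximising, plus the Gaussian
weight, keeps the procedure exploring and prevents it from locking onto
an early wrong estimate; a robustness test removes the weighting
(sd → ∞) and recovery still succeeds, confirming it is an efficiency
device, not a correctness device. Candidates within 2 Cams of the
previous trial's masker are excluded to avoid querying near-duplicate
information; the radius is compared against the most recently presented
masker only.

## Session protocol

A full run presents 4 practice trials (a weak and a strong masker 3 Cams
below the probe, alternated — clearly audible and clearly masked
examples; the exact practice stimuli are a package choice and are
excluded from inference), then 120 post-practice trials: 100 inference
trials — a fixed 16-trial initial grid (eight levels from −20 to +9 dB
re the probe level at 2 Cams below the probe, repeated at 4 Cams) whose
responses do enter the posterior, followed by 84 actively selected
trials — with 20 signal-absent catch trials interleaved at positions
drawn once at session start. Trial logs, per-trial MAP and queried-
information traces, and the final posterior are all returned; a logged
session can be replayed to the identical posterior because the
likelihood is exchangeable.

Two optional refinements follow the recommended strategy for unreliable
responders: with `adaptive_sd`, the likelihood slope is 3 dB for the
first ten active trials and thereafter the running estimate from the
slope diagnostic, floored at 2 dB, with a restart flag above 20 dB; with
`early_stop`, the run ends once the queried information has stayed below
0.1 bit for three consecutive active trials (three in a row so one
lucky quiet trial cannot stop the test).

## Quick TEN(HL) screening

The screening cascade fixes the probe for the adaptive test. At each of
the frequencies where the audiogram reaches 65, 70 and 75 dB HL, the
probe (10 dB above its threshold) is presented in TEN at the matching
level for 10 signal and 10 noise-only trials in random order; at least
15 of 20 correct passes the tier (equivalently X + Y ≥ 1.5 on the hit
and correct-rejection proportions). The first failing tier indicates a
dead region there and fixes (f_sig, l_sig). Ears whose loss never
reaches 65 dB HL are not testable by this cascade; ears passing every
reachable tier get a "no DR detected" outcome.

## Simulated listeners

The cohort generator emulates the study conditions the procedure is
designed for: sigmoidal (on the Cam axis) high-frequency losses with
low plateaus of 10–40 dB HL, high plateaus of 80–110 dB HL, audiogram
slopes at the 65-dB-HL point log-spread over 14–145 dB/octave, true
edges log-spread over 0.5–3.3 kHz, OHCL uniform between 10 dB and
HL_total(f_e) (capped at 65), psychometric slopes of 3 dB with two
outliers near 10 dB, and false-alarm rates of 1% with two tinnitus-like
listeners at 17% and 10%. The distance from the edge to the 65-dB-HL
point is the largest value in 0.8–2.5 Cams that keeps the probe audible
in quiet by at least 3 dB at the edge place — the generator's analogue
of the audibility check a clinical protocol performs before testing.
Responders answer by drawing from the same likelihood the engine uses
(with their own slope and lapse), and Bernoulli(false-alarm rate) on
catch trials; a `broadening` multiplier can desynchronise the
responder's filter broadening from the engine's by ±25% to probe model
mismatch.

What passing recovery tests shows, therefore, is internal consistency:
when a listener behaves like the model, 50–100 trials pin the edge to
within 0.3 Cams. Real listeners differ in ways the generator does not
emulate — attention lapses that drift over time, criterion shifts,
losing track of the probe, non-roex filter shapes — so simulated
accuracy is an upper bound on clinical accuracy.

## Consistency diagnostics

Three post-hoc checks mirror how one would audit a run: the false-alarm
rate over catch trials; the psychometric slope, estimated by expressing
every inference trial's masker level relative to the tuning curve of the
MAP parameters and fitting a probit curve in relative level (a
penalised-maximum-likelihood fit of the same Gaussian-CDF response
family, with a weak ridge on the location; this is the simplest member
of the latent-linear-model class one could also fit with a linear-kernel
Gaussian process) with iterative outlier rejection — yes responses more
than 3 current-sd above the curve and no responses more than 3 sd below
are discarded and the fit repeated, first pass at 3 dB, with the outlier
set recomputed from the full data each pass so points can re-enter if
the estimate grows; and three convergence curves over the trial
sequence: the mean negative log posterior-predictive probability of all
observed responses given the first N trials, the folded ratio of the
N-trial estimate to the final one, and the per-trial queried
information. Perfectly separated data drive the slope estimate toward
zero and set a flag; estimates above 20 dB indicate responses unrelated
to level and a restart is advised.

## Numerical choices and edge cases

* Band integrals: exact closed form (see above); `uniroot` at 1e−9
  tolerance for tuning-curve levels; levels outside 20–90 dB HL make a
  tuning-curve point undefined rather than extrapolated.
* Log-space posterior updates with one exponentiation per trial; the
  lapse floor keeps every likelihood in [0.01, 0.99], so mass can never
  vanish entirely.
* MAP ties break toward the lower f_e bin (the conservative choice for
  a hearing-aid cutoff).
* Catch trials re-present the previous masker with the probe omitted;
  the responder's answer is a false-alarm draw, so the choice of catch
  stimulus does not affect inference.
* Maskers whose band would extend below 20 Hz are truncated and
  renormalised; OHCL above 65 dB is clipped with a warning (broadening
  saturates there).
* The selection weight is computed on the Cam scale, where its 1.5-Cam
  sd is defined.

One consequence of band-averaged excitation through an asymmetric
filter is that the predicted PTC minimum sits slightly *below* f_e for
strongly broadened filters: about 0.24 Cams at OHCL 20 dB, growing to
about 0.56 Cams at the 65-dB cap. The broad lower skirt captures more
of the noise band, so centring the band a little below the edge masks
most efficiently. This does not bias the estimator — inference compares
full response patterns, not tip locations — but it is worth knowing
when comparing predicted tuning curves with tip-picked PTC estimates.

## Validation problem sizes

The shipped tests validate recovery with 50 seeded full sessions (124
trials each) for each of the nine typical cohort members (3-dB slope, 1%
false alarms), requiring the running estimate to sit within 0.3 Cams of
the truth from trial 50 onward in at least 90% of runs per profile;
selection randomisation is checked against exact weights with a
chi-square test over 1e5 draws; sequential updates are checked against
a brute-force batch product on a 6-cell support at 1e−12; and the slope
estimator is checked over 50 replicates of 100-trial probit data. These
sizes were chosen so the whole suite runs in a few minutes on one core
while keeping every Monte-Carlo criterion comfortably powered.

## Known limitations

* The excitation model's coefficients are internal calibrations chosen
  for qualitative fidelity; absolute predicted masked thresholds are not
  validated against listeners.
* Only basal (high-frequency) dead regions are handled; the probe must
  lie above the edge.
* The audiogram is an input, assumed accurate; errors in HL_total
  propagate directly into the audibility constraint and the
  max(E_noise, HL_total) substitution.
* Inference assumes response exchangeability; drifting criteria or
  fatigue violate it and surface only through the diagnostics.
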