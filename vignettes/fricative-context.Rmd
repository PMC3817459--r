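---
title: "Fricative context effects: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fricative context effects: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fricshift)
```

This vignette documents the science inside `fricshift`: the stimulus
model, the generative listener model, the fitting and reporting machinery,
and — because several pieces of the design were genuinely open — the
numerical and structural choices the package makes and why.

## The stimulus model

### Continuum interpolation

A fricative step is three spectral peaks (SP1–SP3), each with a center
frequency (Hz), a bandwidth (Hz), and a level in dB relative to SP2.
The /ʃ/ endpoint is (2932, 6130, 8100) Hz with bandwidths
(1500, 3500, 2520) Hz and levels (+5/3, 0, −5/3) dB; the /s/ endpoint is
(6300, 8200, 9700) Hz, (2000, 3500, 4000) Hz, (−5, 0, +5) dB. Intermediate
steps interpolate frequencies and bandwidths **geometrically** (equal
ratios per step, i.e. linearly in log frequency, matching how the auditory
system spaces frequency) and levels **linearly in dB**. Two consequences
worth knowing:

* endpoints are reproduced exactly, and the middle step of an odd-length
  continuum is the geometric mean of the endpoints (SP1 at step 5 is
  `r round(sqrt(2932 * 6300), 1)` Hz, which prints as 4298);
* the relative-amplitude endpoints are stored exactly as ±5/3 and ∓5 dB;
  printed tables that show 1.67 or −1.7 are roundings of these.

### Rendering

`synthesize_fricative()` shapes a white-noise draw in the spectral domain:
the target power spectrum is the **incoherent sum** of three
Butterworth-magnitude bands, |H(f)|² = 1/(1 + ((f−c)/(bw/2))⁶), weighted by
10^(level/10). The relative amplitude of a peak is thus interpreted as its
**peak spectral density re SP2**, which is the only reading that survives
band overlap (see Limitations). A linear 115 ms rise and 18 ms fall shape
the 180 ms token, and the result is normalized to −3 dBFS peak (free-field
presentation levels have no digital meaning).

We deliberately do **not** bandpass copies of a single noise draw and add
them: where bands overlap — and SP2's 3500 Hz band overlaps SP3's center at
every step — identical noise filtered through two different phase responses
interferes coherently and corrupts the realized levels by several dB.
Spectral-domain shaping reproduces the analytic composite spectrum to
within the periodogram noise floor (the tests bound the deviation at
1.5 dB in matched narrow bands).

### Vowel contexts

The original paradigm spliced the fricatives onto natural vowel recordings,
which cannot be redistributed. `synthesize_vowel()` provides parametric
stand-ins: a glottal pulse train (F0 210 Hz female / 120 Hz male, −6
dB/oct source tilt, faint seeded aspiration) through three cascaded formant
resonators with textbook steady-state formants (/i/: 270–310, 2290–2790,
3010–3310 Hz; /u/: 300–370, 870–950, 2240–2670 Hz across genders). The
first 50 ms carry a formant transition whose F2/F3 onsets are raised
(+250/+400 Hz) for /s/-appropriate transitions and lowered for
/ʃ/-appropriate ones. These defaults are documented as **not** matching any
original talker; they exist so the full pipeline is runnable and so the
factor structure (gender, vowel, transition) has an acoustic correlate.
`assemble_token()` joins fricative and vowel with a 5 ms equal-power
crossfade, preserving total duration to the sample.

## The vocoder

`vocode()` implements the standard envelope vocoder used to simulate CI
hearing. Channels are spaced by the Greenwood map
F(x) = 165.4·(10^(0.06·x) − 0.88) on a 35 mm cochlea: the places of 150 and
10000 Hz are divided into `n_channels` equal-place segments, giving corner
frequencies (8 channels) of 150, 314, 570, 967, 1586, 2549, 4046, 6376,
10000 Hz after rounding; unrounded edges are used internally. Band filters
are causal Butterworth cascades (3rd-order high-pass × 3rd-order low-pass
per band, a 6th-order bandpass realized in a form that stays numerically
stable for the narrow lowest channels). Envelopes are half-wave
rectification followed by a causal 4th-order 300 Hz low-pass; carriers are
independent per-channel white-noise draws filtered through the same bank;
each channel's modulated carrier is scaled so its RMS equals the
analysis-band input RMS over the full token. Causal (not zero-phase)
filtering matches what a real-time processor does.

Tunable parameters, with defaults: `n_channels` (8 — chosen in the CI
literature to approximate implant-user performance), `lo_hz`/`hi_hz`
(150/10000 Hz, widened above typical processors to cover the fricative
spectrum), `env_cutoff_hz` (300 Hz, enough to carry F0), `filter_order`
(6).

One physical caveat documented here because users often expect otherwise:
a tone near a channel corner (e.g. 1 kHz, 3.4% above the 967 Hz corner)
excites the two adjacent channels almost equally — Butterworth neighbors
cross near −3 dB at the corner regardless of order — so its vocoded energy
is split across the corner pair, not confined to one channel. The tests
assert the true behavior (the 967–1586 Hz channel is the energy maximum
and the corner trio carries >80%).

## The generative listener

`simulate_trials()` draws binary /s/ decisions from

$$P(\text{/s/}) = \mathrm{logistic}\big(b_0 + u_{subj} + b_x x + \textstyle\sum_c \beta_c z_c\big),
\qquad u_{subj} \sim N(0, \sigma_u^2),$$

where \(x = \log(\mathrm{SP1}) - \log(f_{med})\) is the centered log-Hz
position of the first spectral peak and \(z_c\) are treatment dummies for
the context factors (reference levels: female voice, /i/ vowel, /ʃ/
transitions, rounded lips, female face). The 4AFC word is the fricative
decision combined with the veridically perceived stimulus vowel.

Defaults and rationale:

* `f_med` = the continuum's median SP1 value (geometric mean of the
  endpoints, ≈ 4298 Hz), so x = 0 at step 5;
* `b_x = 8` logits per log-Hz unit: the smallest round value at which the
  endpoint steps are identified with probability ≥ 0.95 at baseline,
  matching near-ceiling endpoint identification in real listeners
  (any b_x ≥ 7.7 satisfies the constraint);
* `sigma_u = 0.5` logits: a moderate between-listener spread; no empirical
  variance estimates exist to calibrate it, so it is configurable;
* subject counts default to 10 (normal-hearing analog) and 7 (CI analog);
  5 repetitions per token;
* context effects are specified **in Hz** and converted with
  `calibrate_coefficient()`: β = −b_x·log((f_base+Δf)/f_base) moves the
  analytic 50% boundary by exactly Δf. `default_params_exp1()` installs
  702 / 282 / 242 Hz for voice gender, vowel and formant transition, the
  reference magnitudes for normal-hearing listeners in this paradigm.

What the generator emulates: boundary placement, context-additivity on the
logit scale, between-subject intercept variation, binomial trial noise.
What it does not: lapse rates, learning or fatigue across blocks, response
bias among the four words, vowel misperception, audio-visual integration
mechanics (face and lip-rounding effects are additive logit terms only),
and any dependence of responses on the actual rendered audio. Passing
tests therefore demonstrate that the **analysis machinery** recovers known
truths from data of this structure — not that human listeners behave this
way.

## Fitting, selection and the Hz common currency

`fit_logistic()` is trial-level Bernoulli ML (IRLS via `glm`); complete
separation is flagged when any |estimate| > 15. `fit_mixed_logistic()`
uses `lme4::glmer` (Laplace by default, adaptive Gauss–Hermite via
`n_agq`); trials are first aggregated to binomial counts over unique
subject × covariate cells, which leaves estimates and standard errors
unchanged while making repeated fits fast. Because the aggregation always
groups by **every** covariate column (not just the model's terms), the
binomial normalizing constant is identical across candidate models and AIC
differences remain valid.

`forward_select()` starts from the intercept-only model and greedily adds
the candidate with the lowest AIC, stopping when the best improvement is
≤ `delta_threshold` (default 2 AIC units — the conventional "substantial
support" margin). Interactions become eligible only when both parents are
included. All candidate single-term additions here cost exactly one
parameter, so ranking by AIC at the first step is identical to ranking by
deviance/entropy. The full evaluation trace is returned so users can
compare selected structures rather than trusting a single path.

`crossover()` solves the fixed-effects (population-average) linear
predictor for x at P = 0.5 — random intercept at its mean of zero — and
maps back to Hz as f_med·exp(x₅₀). It is implemented by two-point
prediction, so it remains exact when x-by-context interactions are in the
model (the slope then depends on the context levels). `shift_table()`
reports, per factor, boundary(reference) − boundary(alternative) with all
other factors at reference; a factor not selected into the model reports
exactly 0 Hz, mirroring how such tables print structural zeros for
unsupported effects.

## Statistical precision of shift recovery

At the default experiment scale (10 subjects × 144 stimuli × 5 reps =
7200 trials) the steep psychometric slope concentrates information on the
two steps nearest the boundary. The resulting ML standard error of a
context coefficient (~0.07 logits) corresponds to a recovered-shift
standard deviation of roughly 35 Hz. Users should therefore expect the
small (≈250 Hz) effects to be recovered with ~15% relative error *per
replicate*, and spurious context terms admitted at the AIC+2 margin to
carry apparent shifts of 60–100 Hz. Tight recovery claims need several
times this trial count; the test suite's recovery checks document exactly
this behavior at 20 seeded replicates.

## Numerical choices and degenerate inputs

* Filters are designed with `signal::butter`; narrow low-frequency bands
  use high-/low-pass cascades because direct transfer-function bandpass
  designs are ill-conditioned there.
* All stochastic operations take an explicit integer seed and restore the
  caller's RNG state; identical seeds give bit-identical output.
  Pipeline stages derive their seeds from a master seed by a fixed
  counter scheme.
* Silence in → silence out holds throughout (vocoder channels with
  analysis RMS below 1e−9 are skipped).
* WAV I/O is a minimal mono RIFF codec (float32 lossless, PCM16 within
  2⁻¹⁵); clipped samples are an error on write, truncated or malformed
  files raise a structured condition on read.
* Degenerate psychometric inputs: single-response-value tables are
  rejected; a single subject silently degrades the mixed fit to the fixed
  fit with a warning; rank-deficient designs name the aliased terms.
* Test and example problem sizes (24 kHz audio for signal tests, 20-trial
  fixtures for likelihood oracles, 20 seeded replicates for recovery
  checks) are chosen to exercise every code path at interactive speeds.

## Known limitations

* With the published continuum parameters, the three "peaks" overlap so
  strongly that the composite spectrum is nearly a tilted plateau; band
  levels measured on the composite match the analytic mixture, not the
  nominal per-peak levels, and no additive synthesis can make them do
  otherwise. The morph is still clearly expressed as a monotone tilt
  change (density falls at 2932 Hz and rises at 9700 Hz across steps).
* The vowel stand-ins are schematic; analyses that depend on fine
  vowel acoustics should substitute real recordings via `read_wav()` and
  `assemble_token()`.
* The simulator's additivity assumption means interaction effects in
  fitted models reflect sampling noise unless the user injects them.
* Crossovers use fixed effects only; conditional (per-subject) boundaries
  are not reported.
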