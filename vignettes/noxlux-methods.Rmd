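---
title: "Methods: rest-activity rhythms and sleep-EEG analysis under dim light at night"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rest-activity rhythms and sleep-EEG analysis under dim light at night}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(noxlux)
```

noxlux analyses the two data streams of a rodent dim-light-at-night (DLAN)
study — passive-infrared (PIR) rest-activity counts and two-channel EEG/EMG
sleep recordings — and ships a synthetic-data module that simulates both
streams with known ground truth, so that every analysis stage can be
verified end to end without access to raw recordings. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic data can and cannot tell you about real recordings.

## Study design being emulated

Animals live under a 12:12 h light:dark cycle (75:0 lux) or a 12:12 h
light:DLAN cycle (75:5 lux), lights on at 10:00. Zeitgeber time (ZT) 0 is
lights-on; the light phase is ZT [0, 12) and the dark/dim phase ZT [12, 24).
Rest-activity is analysed over 15-day windows in 1-minute bins. Sleep is
recorded as a 24-h baseline day followed by a day that starts with 6 h of
enforced wakefulness ("gentle handling") from light onset and an 18-h
recovery. Lux values are labels only: the package models no photoreceptor
transduction, melatonin, temperature or feeding.

## Rest-activity generator

`simulate_activity()` builds a continuous intensity and draws Poisson counts
around it, rectified at zero:

* a **circadian waveform**: a cosine peaking mid-dark (ZT18), with relative
  amplitude `circadian_amplitude` (default 0.9);
* a **dark-onset surge**: a sharp Gaussian burst (width 0.5 h) at dark
  onset, amplitude `surge_frac` (default 4.2) times the baseline rate,
  scaled by the effective amplitude. Nocturnal rodents reliably produce
  this burst, and it matters analytically: its harmonic content is what
  pins the periodogram fold to the true 24.0-h period at 0.05-h grid
  resolution. A smooth waveform alone leaves the grid argmax free to wander
  by one step under the fractal background;
* a **1/f^β fractal component** (`fractal_noise()`): spectral synthesis —
  Gaussian random spectrum shaped to amplitude f^(−β/2), inverted, and
  standardized — giving an exact target spectral exponent at O(N log N)
  cost, unlike recursive fractional-Gaussian-noise generators. For such
  noise the DFA scaling exponent is α = (β + 1)/2. The component is scaled
  to `fractal_sd_frac` (default 1.5) times the baseline rate: a
  within-night coefficient of variation near one, which is what PIR count
  series look like, and the regime in which the 3–8 h DFA fluctuations are
  dominated by the fractal component rather than by the deterministic
  light/dark transitions. With a substantially smaller fractal share, the
  day/night steps alone inflate α well above its nominal target;
* **phase delay** (`phase_delay_h`): the waveform and surge — not the
  fractal component — are shifted later, emulating the delayed activity
  onset under DLAN. The activity-weighted mean phase shifts by the same
  amount;
* **disruption** (`disruption` in [0, 1]): scales the circadian amplitude by
  (1 − disruption), adds white night-phase noise proportional to
  disruption, and flattens the effective fractal exponent,
  β_eff = β(1 − disruption/2). The third effect deserves a note: additive
  white noise alone barely changes α over 3–8 h windows, because pink
  fluctuations grow like n while white ones grow like √n and the windows
  hold 180–480 bins. Degrading the correlation structure itself is both the
  mechanism that actually lowers α and the more faithful model of what a
  weakened circadian network does to behaviour.

Defaults (`mean_rate` 50 counts/bin, amplitude 0.9, β = 1, 15 days) describe
a healthy control mouse; the generator's own contracts — α recovers
(β + 1)/2 within ±0.05 at zero amplitude for β in {0, 1, 2}, α near 1 under
the full control condition, an exact 24.0-h periodogram peak, and strictly
decreasing α and rhythm strength along a disruption gradient — are enforced
in the test suite over seed ensembles.

## Periodogram

`periodogram()` folds the trace at every candidate period (default grid
20–28 h in 0.05-h steps; each period must be a whole number of bins) and
computes eta-squared: the fraction of total variance explained by the
folded mean waveform. This is the Sokolove–Bushell chi-square periodogram
statistic on a 0–1 scale; N·η² is compared against the chi-square null with
(classes − 1) degrees of freedom, Bonferroni-corrected across the grid by
default so that "no significant rhythm" is a meaningful statement over a
161-period scan. The peak period is the grid argmax and the rhythm strength
is η² at the peak.

Because the original F-periodogram formula used with Actimetrics data is
not public, absolute strength values here are comparable **within this
package only**; orderings across conditions and significance calls are the
meaningful outputs, not the absolute numbers.

## Detrended fluctuation analysis

`dfa()` implements DFA-1: mean-centre, cumulatively integrate to the
profile, split into non-overlapping windows of size n (forward pass,
leftover tail discarded), detrend each window by ordinary least squares,
and pool the root-mean-square residual into F(n). Window sizes are
log-spaced, about 16 inside the fit range plus diagnostic sizes outside;
α is the OLS slope of log10 F(n) against log10 n restricted to the fit
range. The default fit range is 3–8 h — the circadian scaling range; with
15-day traces, windows above 8 h fall below four repetitions and are not
statistically reliable, which is why the range stops there. Shorter traces
are allowed: sizes with fewer than four windows are dropped from the fit
with a warning. Constant input is an explicit error (F(n) would be zero).
The algorithm is exactly invariant to positive affine transforms of the
input, and the test suite pins every F(n) against a brute-force
loop-and-`lm()` reference to 1e-10 relative.

## Sleep-EEG generator

`simulate_recording()` draws a ground-truth hypnogram, integrates the sleep
homeostat over it, and synthesizes 128-Hz EEG and EMG in 4-s epochs.

**Hypnogram.** A first-order Markov chain over WAKE/NREM/REM at 4-s
resolution, with separate transition matrices for the light and dark/dim
phases (`default_transition_matrices()`; direct WAKE→REM transitions are
zero by convention, configurable). Two modulations act on the chain:

* a **dark-phase waking drive**: a circular Gaussian bump (width 1.5 h)
  peaking 1 h after dark onset plus `phase_delay_h`, which pulls the WAKE
  self-transition toward 1. This gives the dark phase a well-defined waking
  peak whose programmed delay `waking_peak()` can recover;
* **sleep-pressure feedback** (`sleep_pressure_coupling`, default 1): the
  homeostat level S scales the WAKE→NREM entry up and the NREM→WAKE exit
  down as (S/0.5)^k, clipped to [0.25, 3]. Without this coupling the chain
  is memoryless and enforced wakefulness would produce no NREM rebound;
  with it, the post-deprivation rise in sleep pressure expresses itself in
  more and longer NREM episodes, as it should.

**Homeostat.** Two-exponential Process-S dynamics
(`homeostat_params()`): S relaxes toward 1 during WAKE and REM with
τ_rise = 8 h and toward 0 during NREM with τ_decay = 2 h, from s0 = 0.5,
integrated per epoch and continuous across epochs
(`process_s_trajectory()`). The literature motivates the two-process
picture but prescribes no specific dynamics; these constants were chosen
once to give a clearly visible rebound in the first 2-h bin after a 6-h
deprivation and are not fitted to anything.

**Signals.** Each 4-s EEG epoch is synthesized in the frequency domain as
band-limited Gaussian components: Hermitian spectra with Rayleigh
amplitudes whose expected per-bin power follows the state's spectral
template (`default_state_templates()`: delta-rich NREM with its maximum
inside 0.75–4.0 Hz, theta-rich REM with its maximum inside 6.25–9.0 Hz,
broadband WAKE with moderate theta, all over a 1/f background). The NREM
0.5–4 Hz amplitude is multiplied by `gain · S(t)`, so measured slow-wave
activity tracks the homeostat. EMG is white Gaussian at a per-state RMS
(WAKE ≫ NREM ≥ REM). A small flat spectral tail above 25 Hz keeps the
signal from being perfectly band-limited. Optional artifact injection
(`artifact_rate`) adds large single-epoch spikes and records them in the
ground-truth flags.

**Sleep deprivation.** `sd_protocol(start_zt_h = 0, duration_h = 6)` forces
every epoch of the window on the last simulated day to WAKE; S integrates
through it, which is the entire mechanism of the modelled rebound.

## Spectral analysis

`epoch_and_fft()` computes one 512-point FFT per 4-s epoch with a
rectangular window — no taper, one transform per epoch — so the discrete
Parseval identity is exact: summed bin power equals the epoch's variance
about its own mean (verified to 1e-9 relative per epoch). Bins outside
0.25–25.0 Hz are dropped after scaling, leaving 100 bins at 0.25-Hz
centres; band edges are inclusive on both sides, so "delta 0.75–4.0 Hz"
means the bins at 0.75, 1.00, …, 4.00 Hz. Spectra are reported in absolute
µV²; normalization to each recording's mean total power is an opt-in flag
of `state_spectra()` because the normalization used in published
state-spectra figures is not stated.

Two slow-wave-activity presets are shipped (`band_presets()`): `swa`
(0.5–4.0 Hz, the timecourse-figure convention) and `swa_delta`
(0.75–4.0 Hz, the delta-band convention); neither is asserted as "the"
definition since the source conventions themselves differ.

`detect_artifacts()` flags epochs whose EEG peak deviation exceeds k = 6
robust SDs (MAD) of the recording, or that are flatline. The criterion is
this package's own invention — the emulated workflow only states that
artifact epochs were excluded from spectral averages — and flags annotate,
never delete: vigilance states are always determinable, and artifact
epochs are excluded only from spectral means (`band_power()`,
`state_spectra()`, `swa_timecourse()`, which reports empty bins as missing,
never zero).

## Vigilance scoring and aggregation

`score_epochs()` replaces visual scoring with a deterministic rule
cascade: EMG above its adaptive threshold → WAKE; otherwise
theta/delta ratio above its adaptive threshold → REM; otherwise NREM.
Thresholds come from a deterministic bimodal split (Otsu's criterion) of
the log EMG distribution and of the log theta/delta ratio among low-EMG
epochs; if a distribution shows no usable bimodality the scorer falls back
to fixed quantiles with a warning. A 3-epoch majority filter (disable-able)
suppresses single-epoch flicker. Accuracy is measured only against the
simulator's ground truth — the suite requires at least 90% epoch agreement
on default recordings — and no claim is made of replicating human scoring.

Aggregation conventions: ZT-aligned half-open bins [start, end); state
percentages per 2/6/12/24-h bin sum to 100 exactly; interval labels L1/D1
(baseline light and dark halves) and L2/D2 (the post-deprivation day), with
the 6-h post-deprivation light segment compared against the same clock-time
baseline segment. `waking_peak()` reports the midpoint of the maximal 2-h
WAKE bin inside the search interval (default the dark half), ties to the
earliest bin — the source resolution of published timecourses is 2 h, so no
finer peak estimate is pretended. `daily_amplitude()` is the dark 12-h mean
minus the light 12-h mean, per state.

## Statistics

`anova_table()` fits fixed-effects linear models (1–3 factors, interactions
by flag) and reports Type-II sums of squares — the sensible default for the
unbalanced group sizes (n = 5 vs n = 9) this design produces; the emulated
analyses do not state their SS type. `anova_from_summary()` computes the
one-way F directly from printed group means/SDs/sizes, which is how
published group results can be re-tested without raw data.
`bonferroni_ttests()` runs a declared comparison plan (Welch's t by
default — robust to the unequal variances these groups show; pooled
variance by flag; paired t where flagged) and adjusts p by the plan size m,
capped at 1. The plan is explicit because the emulated analyses corrected
per figure-level family, not globally. `fit_delay_regression()` is ordinary
least squares of waking-peak time on an exposure index coded 1..k for
increasing exposure durations (e.g. 1–4 for 0, 1, 7, 30 days), with
coefficient SEs and R². All three are pinned in the test suite against
from-scratch sums-of-squares, closed-form Welch, and closed-form OLS
oracles to 1e-8, and slope CI coverage is verified by simulation.

## Pipeline

`run_pipeline()` executes the whole design from one config (defaults in
`default_config()`, YAML via `read_config()`, CLI wrapper in
`inst/scripts/noxlux`): per arm, simulate activity → periodogram + DFA;
simulate baseline + deprivation recordings → spectra → artifacts → scoring
→ timecourses + SWA + rebound; then one-way ANOVAs across arms, t-tests
against control, and the peak-delay regression. Per-animal seeds derive
from the master seed, so the bundle is reproducible bit for bit; any stage
failure aborts with the stage name. The default arm table is a five-arm
exposure ladder (control plus four DLAN durations) with programmed waking
delays spanning 2–8 h, a disruption gradient, and exposure indices 1–4 for
the regression (the longest-exposure arm has no usable waking peak and is
excluded from it).

## Problem sizes and runtime

The analysis conditions are the study's own: 15-day, 1-min-bin activity
traces (21,600 bins) and full-day 128-Hz recordings (21,600 4-s epochs per
day). Activity analyses take seconds; one simulated day of EEG costs a few
seconds to generate and a few to epoch and transform, so the acceptance
checks that sweep all five arms with two-day recordings run in a couple of
minutes. The test suite's pipeline checks use a reduced two-arm, 4-day
configuration purely to keep the end-to-end contract fast; nothing in the
method depends on those sizes.

## Limitations

* The synthetic data are stationary within phase, Gaussian in their
  spectral components, and Markovian in state structure. Real recordings
  drift, contain movement and electrode artifacts of many shapes (only
  amplitude spikes are modelled), and have bout-duration distributions with
  heavier tails than a first-order chain produces. Passing tests therefore
  demonstrate correctness of the *analysis chain*, not field performance of
  the scorer or artifact detector on real data.
* Periodogram strength is package-internal; do not compare absolute values
  against results computed with other periodogram statistics.
* DFA is DFA-1 only, non-overlapping forward windows; no multifractal
  extension, no higher detrending orders, no unevenly-sampled
  (Lomb–Scargle) support.
* The rest-activity generator is entrained at exactly 24 h; free-running
  periods are only exercised by injecting a non-24-h gate directly in the
  tests.
* The delay regression against exposure index cannot be validated against
  real observed peaks (they are not published); it is validated by
  synthetic recovery of programmed delays instead.
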