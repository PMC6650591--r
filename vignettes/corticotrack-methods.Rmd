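---
title: "Models and methods behind corticotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind corticotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticotrack)
```

## The scientific problem

Slow cortical activity aligns its phase to the amplitude envelope of heard
speech, and this "envelope tracking" is classically stronger in the right
auditory cortex at syllable-rate (theta) frequencies. corticotrack packages
the analysis chain used to quantify that tracking and its lateralization —
phase-locking value (PLV), hemispheric asymmetry index, trial-wise spectral
coherence, and frontal–auditory phase-lag connectivity (wPLI/dwPLI) — along
with a generative model of a cohort in which the tracking arises from two
distinct mechanisms:

* an **intrinsic auditory** mechanism: the right auditory channel is a
  noisy phase oscillator with a natural frequency in the theta range that
  entrains to the stimulus rhythm only within a restricted detuning range
  (an Arnold tongue);
* an **externally driven** mechanism: the left auditory channel follows
  the stimulus envelope through a top-down gain relayed from a frontal
  region, independently of the stimulus rate.

Because the interplay of the two mechanisms is expressed entirely through
per-subject parameters with recorded ground truth, each of the three
experiment designs (rate tuning, connectivity–asymmetry correlation,
semantic condition contrast) can be replayed end to end and checked for
parameter recovery.

## The forced phase oscillator

The intrinsic mechanism uses the minimal dynamical system satisfying the
two defining properties of a neural oscillator — self-sustained rhythmicity
at a natural frequency, and synchronization to external rhythms near that
frequency — namely the stochastically forced Kuramoto/Adler phase model

$$ d\theta = \bigl[\,2\pi f_{nat} + K \sin(\theta_{env}(t) - \theta)\,\bigr]\,dt
   + \sigma\, dW, $$

integrated by Euler–Maruyama at the recording sampling rate (the
integrator precondition `fs >= 20 f_nat` keeps the discretization error in
the locked-phase lag below 0.01 rad; tests verify the noiseless fixed point
`asin(\Delta\omega / K)` to that tolerance). With `sigma = 0` the model
locks exactly when `|2\pi(f_{stim} - f_{nat})| <= K`, giving a closed-form
Arnold tongue that the test suite checks on a 7 × 7 detuning–coupling
grid. Outside the tongue the oscillator's instantaneous frequency is
periodically pulled toward the stimulus (phase trapping), which leaks
stimulus-coherent power into neighbouring analysis bands; this is why the
simulated right-hemisphere tuning curve falls off smoothly rather than as
a step, as empirical tuning curves do.

The stimulus phase used for forcing is computed by the same
`narrowband_phase()` operation the analysis stage uses, so generator and
analyzer agree on what "the envelope phase" means.

## The synthetic subject

`simulate_subject()` produces three channels at the stimulus rate:

* `audR = cos(θ_R) + noise`, `θ_R` the entrained oscillator;
* `audL = w_left · cos(θ_L) + g_td · envband(t − τ) + noise`, with
  `envband` the stimulus envelope band-passed around the syllable rate,
  RMS-normalized to the amplitude of a unit cosine, and delayed by a fixed
  neural delay `τ` (default 20 ms); `θ_L` a weak, spectrally broad left
  intrinsic oscillator (unlocked, high phase diffusion);
* `frontal = c_frontal · envband(t − τ − lag_j) + noise`, the same
  envelope-band signal lagged by `frontal_lag_s` (default 50 ms, ≈ 81° at
  4.5 Hz, chosen so the frontal–auditory cross-spectrum has a strong
  imaginary part) plus a per-trial lag jitter (SD 20 ms) representing
  trial-to-trial variability in fronto-auditory conduction delay.

Measurement noise is white Gaussian (the field's default assumption absent
a stated noise model); a pink-noise option was considered and rejected to
keep the per-band noise floor flat across analysis bands, which is what
makes the left-hemisphere percent-change profile flat by construction
rather than by accident.

A detail that matters: the recorded stimulus envelope carries a small
acoustic noise floor (2 % of the envelope peak). Without it, a silent
pre-stimulus baseline is digital zero, and the zero-phase band-pass filter
rings backwards from the stimulation onset, giving the "silence" a
deterministic phase locked to the upcoming stimulus — an artifact real
recordings do not have. With the floor, baseline phase behaves like
filtered noise in every band.

## Cohort defaults and why

`sample_subject_params()` draws subjects as follows (defaults in
parentheses):

* `g_td ~ Uniform(0, 0.4)`: modest, variable top-down engagement during
  passive syllable listening.
* `c_frontal = c_max · [ρ · g_td/g_max + (1 − ρ) · Uniform(0,1)]` with
  `ρ = 0.8`, `c_max = 0.25`: frontal coupling tied to the top-down gain.
  `c_max` is deliberately small so that the frontal channel — not the
  auditory one — is the signal-to-noise bottleneck of the wPLI estimate;
  this is what makes the wPLI ⟂ asymmetry correlation vanish when `ρ = 0`
  (a null the tests check) instead of being recreated through the shared
  dependence on `g_td`.
* right oscillator: `f_nat = 4.6 Hz` (± 0.15 between subjects),
  `K = 2π · 0.8 rad/s` (5 % log-normal jitter), `σ = 0.7 rad/√s`. The
  tongue then covers 3.8–5.4 Hz: the 4.5 syll/s condition locks strongly,
  5.5 partially, and 2.5/6.5 fall outside. The sizeable phase noise keeps
  off-tongue phase trapping from producing spuriously coherent
  side-band leakage in the 6.5 Hz analysis band.
* left oscillator: unlocked (`K = 0`), `f_nat ~ 4.5 ± 1.5 Hz` uniform,
  `σ = 1.2`, weight `w_left = 0.05`: a weak, broad intrinsic theta
  component that does not by itself track the stimulus.
* `noise_amp = 1.3` relative to the unit oscillator amplitude. Short
  (2 s) windows in a 1 Hz band saturate the PLV near its ceiling at high
  SNR; this noise level places per-window PLV in its informative range.

These defaults were chosen to put the generator in the qualitative regime
the three experiment designs probe — right-lateralized rate tuning with a
flat left hemisphere, an asymmetry that declines with top-down gain, and a
condition contrast that reverses the asymmetry — while keeping every
criterion a genuine statistical outcome rather than a foregone conclusion
(the null configurations of each pipeline stay null; the test suite checks
both directions).

Experiment-specific cohorts override only what their design requires:
the connectivity cohort uses `g_td ~ Uniform(0.3, 1.5)` (strong individual
differences in top-down engagement are the phenomenon of interest there),
and the condition-contrast cohort uses `g_td ~ Uniform(0.1, 0.5)` per
subject with the semantic-analog condition multiplying each subject's gain
by `semantic_boost` (default 3; the boost magnitude is not constrained by
any reported quantity, so it is a free parameter with this documented
default).

## The analysis chain

**PLV.** `plv()` implements
$\mathrm{PLV} = \frac{1}{T}\bigl|\sum_t e^{i(\theta_1(t) - \theta_2(t))}\bigr|$.
`windowed_plv()` band-passes both series (zero-phase Butterworth order 4,
forward–backward), takes analytic-signal phases, tiles the segment with
half-open windows `[start, start + window)` at stride `window − overlap`
(trailing partial window dropped), and averages the per-window PLVs.
Windowing before averaging matters: the per-window estimate is biased
upward at short `T`, so all comparisons hold window parameters fixed
(rate-tuning design: 2 s / 1 s overlap in rate ± 0.5 Hz; connectivity
design: 1 s / 0.5 s in 3.5–5.5 Hz).

**Baseline normalization.** The rate-tuning pipeline simulates a 3 s
silent baseline per trial and reports
`(PLV_stim − PLV_base)/PLV_base`. The first second after stimulation
onset is discarded (oscillator settling), and baseline windows keep 0.5 s
clear of both the trial edge and the stimulation onset, outside the reach
of filter transients and the acausal ring of the zero-phase filter.
The asymmetry index `2(R − L)/(R + L)` is computed from the raw
stimulation-window synchronization values, which are nonnegative by
construction — percent-change values can be negative and would break the
index's `[−2, 2]` bound; percent change is reported alongside.

**Coherence.** `coherence_at_freq()` takes one Hann-tapered complex
coefficient per trial at the FFT bin nearest the target frequency and
forms `|Σ X Y*|² / (Σ|X|² Σ|Y|²)` across trials, with Fisher z
(`atanh`) attached. The squared-magnitude normalized form is used; the
condition-contrast pipeline analyzes 9 s segments, giving the 0.111 Hz
resolution of the design it mirrors. Self-coherence is exactly 1; under
independence the estimate concentrates near `1/n_trials` (tested).

**wPLI.** Two estimators are exposed and never silently mixed.
`wpli_square_time()` is the within-trial form: Morlet coefficients
(default 4.5 Hz, 9 cycles, unit-energy kernel truncated at 3.5 SD, edge
samples excluded), cross-spectrum `X_t = Z_x Z_y^*`, normalized imaginary
part `Y_t = Im(X)/|X|`, and the debiased square
`(|ΣY|² − ΣY²)/((Σ|Y|)² − ΣY²)`. `dwpli_trials()` is the across-trial
debiased form on unnormalized `Im(X)` per trial. Degenerate 0/0 cases
(e.g. purely zero-lag coupling) return 0 with a `degenerate` attribute
rather than erroring, so cohort pipelines survive pathological subjects.
The connectivity pipeline computes the within-trial estimator per trial
and averages across trials; a pooled-time-points alternative is exposed
via `wpli_mode = "pooled"`.

**Cohort statistics.** Outlier exclusion removes points beyond 2 sample
SDs in a single pass, applied per metric within condition before any
test (this mirrors analysis pipelines whose reported N differs between
figures). All tests are two-sided nonparametric ranks: Kruskal–Wallis
across rates, Wilcoxon signed-rank against zero or between paired
conditions, Mann–Whitney between groups, Benjamini–Hochberg FDR across
rates, Spearman rank correlation. Exact small-sample null distributions
are used where tie-free (the suite checks the n = 6 signed-rank and
4-vs-4 Mann–Whitney cases against full enumeration values and the type-I
error of all three tests on 1000 null cohorts).

## Numerical choices

* "Butterworth order 4 band-pass" means `signal::butter(4, ...)` applied
  forward–backward (`filtfilt`), the MATLAB/FieldTrip convention;
  stability was verified for every band/sampling-rate pair the package
  uses.
* The analytic signal is computed by the FFT half-spectrum method; phases
  are wrapped to `(−π, π]` with an unwrapped view kept for slopes and
  lags.
* The 8-band cochlear filterbank spaces band edges uniformly on the
  ERB-rate scale from 100 Hz to `min(8000, 0.45 fs)` Hz — a cochlear
  motivation without a full auditory model; no compressive nonlinearity
  is applied. Envelope resampling to 500 Hz uses polyphase resampling
  after a 200 Hz anti-alias low-pass.
* Seed policy: one master seed; subject `k` uses `derive_seed(seed, k)`,
  trial `j` of a subject uses `derive_seed(subject_seed, j)`, with a
  fixed Lehmer-style integer mix. Every pipeline is a pure function of
  `(config, seed)`; reruns produce byte-identical CSV output (tested).

## Problem sizes

The default cohorts are 17 subjects × 5 rates × 12 trials of 3 + 6 s
(rate tuning), 37 subjects × 8 trials of 10 s (connectivity), and 19
subjects × 2 conditions × 12 trials of 10 s (condition contrast), all
simulated at 200 Hz — sizes chosen to match the cohort sizes of the
designs being emulated while keeping a full 20-replicate recovery
experiment comfortably desktop-sized.

## What passing tests do and do not show

The generator produces band-limited, phase-structured signals with white
measurement noise, identical stimulus envelopes across trials, and a
single frontal channel; it has no 1/f background, no volume conduction or
field spread, no evoked (non-oscillatory) response, no head movement, and
no behavioral variability. Passing recovery tests therefore show that the
analysis chain measures what the generative model encodes — directions of
effects, calibrated nulls, exact estimator algebra — not that real MEG
cohorts would show these effect sizes. Quantities printed by published
analyses of real data (e.g. specific χ² or correlation values) are not
reproduction targets here, since the underlying recordings are not
publicly available; the pipelines assert directional/qualitative
patterns only.

## Known limitations

* The per-window PLV is upward-biased at short windows; between-condition
  comparisons are valid because window parameters are held fixed, but PLV
  magnitudes should not be compared across different window settings.
* The envelope definition (8-band ERB Hilbert average) is one documented
  choice applied uniformly; analyses whose envelope used different band
  counts or compression will differ in absolute coherence.
* `wpli_square_time()` follows the printed within-trial normalized form
  `Y = Im(X)/|X|`; the across-trial `dwpli_trials()` uses unnormalized
  `Im(X)` per the debiased estimator's standard definition. The two are
  not interchangeable and are reported with their mode.
* Exclusion moments (2 SD) are computed per condition; a pooled variant
  is a one-line change but changes which subjects are dropped.
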