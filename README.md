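# corticotrack

Speech–brain coupling, its hemispheric lateralization, and synthetic
entrainment cohorts, in R.

When people listen to speech, slow cortical activity in auditory cortex
phase-aligns to the amplitude envelope of the sound, and this *envelope
tracking* is classically right-lateralized at syllable-rate (theta)
frequencies. Whether that rightward dominance reflects intrinsic oscillatory
properties of right auditory cortex, or is reshaped by top-down input into
the left hemisphere, is a live question. corticotrack is for researchers who
want to (a) quantify envelope tracking and its asymmetry from source-level
electrophysiological time series, and (b) simulate cohorts in which the two
candidate mechanisms are explicit, parameterized, and recoverable.

## What it computes

**Synchronization.** The phase-locking value between brain activity and the
stimulus envelope,

    PLV = (1/T) | Σ_t exp{ i (θ_brain(t) − θ_env(t)) } |,

computed over sliding windows in a narrow band around the syllable rate
(`windowed_plv()`), with percent change from a silent baseline
(`percent_change()`), plus trial-wise spectral coherence at a target
frequency with Fisher z (`coherence_at_freq()`).

**Lateralization.** The hemispheric asymmetry index

    AI = 2 (PLV_right − PLV_left) / (PLV_right + PLV_left)  ∈ [−2, 2],

positive for rightward dominance (`asymmetry_index()`).

**Connectivity.** Frontal–auditory phase-lag coupling by the weighted phase
lag index: the within-trial Morlet-wavelet square estimator
`(|ΣY|² − ΣY²)/((Σ|Y|)² − ΣY²)` with `Y = Im(X)/|X|` (`wpli_square_time()`),
and the across-trial debiased wPLI (`dwpli_trials()`). Both are immune to
zero-lag (volume-conducted) coupling.

**Cohort statistics.** 2-SD outlier exclusion, Kruskal–Wallis / Wilcoxon /
Mann–Whitney rank tests, Benjamini–Hochberg FDR, Spearman correlation
(`exclude_outliers()`, `rank_tests()`, `fdr_bh()`, `spearman_cor()`).

**Simulation.** A syllable-train stimulus generator and a two-mechanism
subject model: the right auditory channel is a noisy forced phase oscillator
(`dθ = [2π f_nat + K sin(θ_env − θ)] dt + σ dW`, locking within the Arnold
tongue `|2π Δf| ≤ K`), the left channel follows the envelope through a
top-down gain relayed by a lagged frontal channel
(`simulate_entrained_oscillator()`, `simulate_subject()`,
`simulate_cohort()`), with ground-truth parameters recorded for recovery
tests.

Three pipelines replay the corresponding experiment designs end to end:
`run_rate_tuning()`, `run_connectivity_cohort()`, `run_condition_contrast()`.

## Worked example

Simulate one subject and measure the lateralized tracking:

```r
library(corticotrack)

spec <- stimulus_spec(rate_hz = 4.5, duration_s = 6, fs_hz = 200)
sp <- subject_params(
  right_osc = oscillator_params(4.6, K = 2*pi*0.8, sigma = 0.7),
  left_osc  = oscillator_params(4.5, K = 0, sigma = 1.2),
  g_td = 0.3, c_frontal = 0.2, noise_amp = 1.3, w_left = 0.05, seed = 42)
rec <- simulate_subject(sp, spec, n_trials = 12)

pr <- windowed_plv(rec$data[1, "audR", ], rec$envelope_rec, 200, c(4, 5), 2, 1)
pl <- windowed_plv(rec$data[1, "audL", ], rec$envelope_rec, 200, c(4, 5), 2, 1)
asymmetry_index(pr$value, pl$value)
#> <asymmetry_index> 0.0179 (right 0.9794, left 0.9620)
```

The right channel (entrained oscillator, natural frequency 4.6 Hz driven at
4.5 syll/s) locks more tightly than the left (noise plus a moderate
envelope-following gain), giving a positive asymmetry for this trial.

Run the full rate-tuning cohort experiment (17 subjects, rates 2.5–6.5
syllables/s, 12 trials each with a 3 s silent baseline):

```r
res <- run_rate_tuning(list(seed = 1))
aggregate(cbind(pc_left, pc_right, asymmetry) ~ rate_hz, res$table,
          function(x) round(mean(x), 3))
#>   rate_hz pc_left pc_right asymmetry
#> 1     2.5   1.491    1.506     0.013
#> 2     3.5   1.153    1.381     0.102
#> 3     4.5   1.153    3.040     0.152
#> 4     5.5   1.058    1.144     0.098
#> 5     6.5   1.175    1.377     0.061
res$stats$kw_right$statistic   # 22.06, p = 2e-4  -> right tuned to rate
res$stats$kw_left$p_value      # 0.10             -> left flat
res$stats$sig_positive_rates   # 3.5 4.5 5.5      -> central asymmetry band
```

The right hemisphere's percent-change PLV peaks at the oscillator's natural
rate and is significantly modulated across rates (Kruskal–Wallis
χ²(4) = 22.06, p = 2e-4); the left hemisphere's envelope-following tracking
is rate-independent (p = 0.10); the asymmetry is FDR-significantly positive
only in a central band of rates.

`run_connectivity_cohort()` additionally returns the Spearman correlation
between frontal–auditory wPLI and the asymmetry index (negative under the
default cohort: stronger top-down coupling, more symmetric tracking), and
`run_condition_contrast()` the paired contrast in which boosting each
subject's top-down gain (the semantic-analog condition) reverses the mean
asymmetry sign. Passing `out_dir` to any pipeline writes the per-subject
metrics CSV and a JSON summary with the resolved configuration.

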