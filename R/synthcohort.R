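#' Specify a syllable-train stimulus
#'
#' A stimulus is a periodic train of smooth (raised-cosine) syllable pulses
#' at `rate_hz` syllables per second. The default syllable duration is
#' `min(0.12, 0.5 / rate_hz)` seconds: 120 ms compressed syllables at slow
#' rates and half the inter-onset interval at fast rates (111 ms at 4.5
#' syll/s), matching common synthesized-syllable protocols.
#'
#' @param rate_hz syllables per second (> 0).
#' @param duration_s total stimulus duration in seconds (>= 2 / rate_hz).
#' @param fs_hz sampling rate in Hz (>= 4 * rate_hz).
#' @param syllable_dur_s syllable pulse width in seconds
#'   (<= 1 / rate_hz so pulses never overlap).
#' @param carrier `"envelope_only"` (default) or `"am_noise"`, in which case
#'   the stimulus also carries an audio waveform: the envelope multiplied by
#'   a band-limited noise carrier.
#' @param seed integer seed used for the noise carrier (the envelope itself
#'   is deterministic).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(rate_hz, duration_s, fs_hz,
                          syllable_dur_s = min(0.12, 0.5 / rate_hz),
                          carrier = c("envelope_only", "am_noise"),
                          seed = 1L) {
  carrier <- match.arg(carrier)
  if (!(rate_hz > 0)) stop("rate_hz must be > 0")
  if (syllable_dur_s > 1 / rate_hz + 1e-12)
    stop(sprintf(
      "overlapping syllables: syllable_dur_s = %g exceeds the inter-onset interval 1/rate_hz = %g",
      syllable_dur_s, 1 / rate_hz))
  if (duration_s < 2 / rate_hz)
    stop("duration_s must cover at least two syllable periods (>= 2/rate_hz)")
  if (fs_hz < 4 * rate_hz)
    stop("fs_hz must be at least 4 * rate_hz")
  structure(list(rate_hz = rate_hz, syllable_dur_s = syllable_dur_s,
                 duration_s = duration_s, fs_hz = fs_hz,
                 carrier = carrier, seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Generate a syllable-train stimulus trial
#'
#' Builds the stimulus envelope as a train of unit-peak raised-cosine pulses
#' of width `syllable_dur_s` at inter-onset interval `1/rate_hz`, starting
#' at t = 0. With `carrier = "am_noise"` an audio waveform is also returned:
#' the envelope amplitude-modulating a band-limited (100 Hz to 0.45 fs)
#' Gaussian noise carrier, deterministic given the spec seed.
#'
#' @param spec a [stimulus_spec()].
#' @return an object of class `stimulus_trial` with fields `envelope`
#'   (unit-peak, nonnegative), `audio` (or NULL), `rate_hz`,
#'   `onset_times_s`, `fs_hz`.
#' @export
make_syllable_stream <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  fs <- spec$fs_hz
  n <- round(spec$duration_s * fs)
  n_onsets <- floor(spec$duration_s * spec$rate_hz)
  onsets <- (seq_len(n_onsets) - 1) / spec$rate_hz
  env <- numeric(n)
  pulse_n <- max(2L, round(spec$syllable_dur_s * fs))
  pulse <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = pulse_n)))
  for (o in onsets) {
    i0 <- round(o * fs) + 1L
    i1 <- min(n, i0 + pulse_n - 1L)
    env[i0:i1] <- env[i0:i1] + pulse[seq_len(i1 - i0 + 1L)]
  }
  env <- env / max(env)
  audio <- NULL
  if (spec$carrier == "am_noise") {
    audio <- with_seed(spec$seed, {
      carrier_noise <- rnorm(n)
      carrier_bp <- bandpass_zerophase(carrier_noise, fs, 100,
                                       min(7000, 0.45 * fs))
      env * carrier_bp / stats::sd(carrier_bp)
    })
  }
  structure(list(envelope = env, audio = audio, rate_hz = spec$rate_hz,
                 onset_times_s = onsets, fs_hz = fs,
                 duration_s = spec$duration_s),
            class = "stimulus_trial")
}

#' @export
print.stimulus_trial <- function(x, ...) {
  cat(sprintf("<stimulus_trial> %.3g s at %g Hz, %d syllables at %g /s%s\n",
              x$duration_s, x$fs_hz, length(x$onset_times_s), x$rate_hz,
              if (is.null(x$audio)) "" else ", with am_noise audio"))
  invisible(x)
}

#' Phase-oscillator parameters
#'
#' Parameters of the forced phase (Adler/Kuramoto) oscillator used for the
#' intrinsic auditory mechanism: it runs at its natural frequency and locks
#' to an external rhythm when the detuning is within the Arnold tongue
#' `|2 pi (f_stim - f_nat)| <= K`.
#'
#' @param f_nat_hz natural frequency in Hz (> 0).
#' @param K coupling strength to the stimulus phase, rad/s (>= 0).
#' @param sigma phase-diffusion intensity, rad/sqrt(s) (>= 0).
#' @param phi0 initial phase in radians.
#' @return object of class `oscillator_params`.
#' @export
oscillator_params <- function(f_nat_hz, K = 0, sigma = 0, phi0 = 0) {
  if (!all(is.finite(c(f_nat_hz, K, sigma, phi0))))
    stop("oscillator parameters must be finite")
  if (f_nat_hz <= 0) stop("f_nat_hz must be > 0")
  if (K < 0 || sigma < 0) stop("K and sigma must be >= 0")
  structure(list(f_nat_hz = f_nat_hz, K = K, sigma = sigma, phi0 = phi0),
            class = "oscillator_params")
}

#' Per-subject generative parameters
#'
#' Bundles the two mechanisms: `right_osc` drives the right auditory channel
#' (intrinsic entrained oscillator); the left auditory channel mixes a weak
#' intrinsic oscillator (`left_osc`, weight `w_left`) with a top-down
#' envelope-following component of gain `g_td`. A frontal channel carries
#' the same envelope-band component scaled by `c_frontal` and lagged by
#' `frontal_lag_s` relative to the left auditory copy.
#'
#' @param right_osc,left_osc [oscillator_params()] for each hemisphere.
#' @param g_td top-down envelope-following gain (>= 0, dimensionless,
#'   relative to the unit-amplitude oscillator signal).
#' @param c_frontal frontal envelope-band amplitude in `[0, 1]`.
#' @param frontal_lag_s frontal lag relative to the left auditory envelope
#'   component, seconds (>= 0).
#' @param frontal_jitter_s SD of the per-trial jitter of the frontal lag,
#'   seconds (>= 0); models trial-to-trial variability of fronto-auditory
#'   conduction/processing delay.
#' @param noise_amp measurement-noise SD relative to unit signal amplitude.
#' @param seed integer subject seed; per-trial streams are derived from it
#'   with [derive_seed()].
#' @param w_left amplitude of the left intrinsic oscillator component.
#' @param env_delay_s fixed neural delay of the envelope-following
#'   components, seconds.
#' @return object of class `subject_params`.
#' @export
subject_params <- function(right_osc, left_osc, g_td, c_frontal,
                           frontal_lag_s = 0.05, frontal_jitter_s = 0.02,
                           noise_amp = 0.5, seed = 1L, w_left = 0.5,
                           env_delay_s = 0.02) {
  stopifnot(inherits(right_osc, "oscillator_params"),
            inherits(left_osc, "oscillator_params"))
  vals <- c(g_td = g_td, c_frontal = c_frontal,
            frontal_lag_s = frontal_lag_s,
            frontal_jitter_s = frontal_jitter_s, noise_amp = noise_amp,
            w_left = w_left, env_delay_s = env_delay_s)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("all subject gains/lags must be finite and nonnegative")
  if (c_frontal > 1) stop("c_frontal must lie in [0, 1]")
  structure(list(right_osc = right_osc, left_osc = left_osc, g_td = g_td,
                 c_frontal = c_frontal, frontal_lag_s = frontal_lag_s,
                 frontal_jitter_s = frontal_jitter_s,
                 noise_amp = noise_amp, seed = as.integer(seed),
                 w_left = w_left, env_delay_s = env_delay_s),
            class = "subject_params")
}

#' Integrate a stimulus-forced noisy phase oscillator
#'
#' Euler--Maruyama integration at step `1/fs_hz` of
#' `d theta = (2 pi f_nat + K * drive(t) * sin(theta_env - theta)) dt
#'  + sigma dW`, i.e. a forced Kuramoto (Adler) phase model. With
#' `sigma = 0` the oscillator locks to the drive exactly when the detuning
#' lies inside the Arnold tongue, with the locked lag `asin(delta_omega/K)`.
#'
#' @param env_phase stimulus phase, a `phase_series` or numeric radians.
#' @param params an [oscillator_params()].
#' @param fs_hz sampling rate; must satisfy `fs_hz >= 20 * f_nat_hz`.
#' @param seed integer seed for the diffusion increments.
#' @param drive optional 0/1 vector gating the coupling term (e.g. zero
#'   during a pre-stimulus silent baseline). Default: always on.
#' @return list with `phase` (a `phase_series`) and `signal = cos(theta)`.
#' @export
simulate_entrained_oscillator <- function(env_phase, params, fs_hz,
                                          seed = 1L, drive = NULL) {
  stopifnot(inherits(params, "oscillator_params"))
  th_env <- if (inherits(env_phase, "phase_series")) env_phase$values else env_phase
  if (!all(is.finite(th_env))) stop("env_phase must be finite")
  if (fs_hz < 20 * params$f_nat_hz)
    stop("fs_hz must be at least 20 * f_nat_hz for a stable phase step")
  n <- length(th_env)
  if (is.null(drive)) drive <- rep(1, n)
  dt <- 1 / fs_hz
  omega <- 2 * pi * params$f_nat_hz
  dW <- if (params$sigma > 0)
    with_seed(seed, rnorm(n, sd = params$sigma * sqrt(dt))) else numeric(n)
  theta <- numeric(n)
  theta[1] <- params$phi0
  K <- params$K
  for (t in 2:n) {
    theta[t] <- theta[t - 1] +
      (omega + K * drive[t - 1] * sin(th_env[t - 1] - theta[t - 1])) * dt +
      dW[t - 1]
  }
  list(phase = phase_series(wrap_phase(theta), fs_hz, unwrapped = theta),
       signal = cos(theta))
}

# Band-passed, RMS-normalized, delayed copy of the stimulus envelope: the
# signal that the top-down (envelope-following) components carry.
envelope_band_component <- function(envelope, fs_hz, rate_hz, delay_s) {
  eb <- bandpass_zerophase(envelope - mean(envelope), fs_hz,
                           max(0.2, rate_hz - 0.5), rate_hz + 0.5)
  s <- stats::sd(eb)
  if (s > 0) eb <- eb / (s * sqrt(2))  # unit peak-equivalent amplitude
  delay_samples(eb, delay_s * fs_hz)
}

#' Simulate one subject's multichannel recording
#'
#' Generates `n_trials` trials of three channels at the stimulus sampling
#' rate: `audL` (weak intrinsic oscillator + top-down envelope component),
#' `audR` (entrained oscillator), `frontal` (lagged envelope component).
#' An optional stimulus-free baseline of `baseline_s` seconds precedes the
#' stimulation segment of each trial; during the baseline the oscillator
#' coupling is gated off and the envelope components are zero.
#'
#' The recording also carries `envelope_rec`, the stimulus envelope as it
#' would be picked up by the audio channel over the whole trial: the clean
#' envelope plus a small acoustic noise floor (`env_noise_floor` times the
#' envelope peak). A silent baseline is therefore low-level noise rather
#' than digital zero, so its narrowband phase behaves like real silence
#' instead of the deterministic ring of a filtered step. Oscillator forcing
#' uses the narrowband phase of this same recorded envelope.
#'
#' @param sp a [subject_params()].
#' @param spec a [stimulus_spec()] describing the stimulation segment.
#' @param n_trials number of trials (>= 1).
#' @param baseline_s silent baseline prepended to each trial, seconds.
#' @param env_noise_floor acoustic noise floor of the recorded envelope,
#'   relative to the envelope peak (default 0.02).
#' @param condition condition label attached to the recording.
#' @return object of class `simulated_recording`: `data` is an array
#'   `trials x channels x samples` with `channel_names`
#'   `c("audL", "audR", "frontal")`; `stimulus` the [make_syllable_stream()]
#'   trial; `truth` the generating [subject_params()]; `baseline_s` as given.
#' @export
simulate_subject <- function(sp, spec, n_trials, baseline_s = 0,
                             env_noise_floor = 0.02,
                             condition = "default") {
  stopifnot(inherits(sp, "subject_params"), inherits(spec, "stimulus_spec"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  fs <- spec$fs_hz
  stim <- make_syllable_stream(spec)
  nb <- round(baseline_s * fs)
  env_full <- c(numeric(nb), stim$envelope)
  n <- length(env_full)
  env_rec <- env_full + env_noise_floor *
    abs(with_seed(derive_seed(sp$seed, 999L), rnorm(n)))
  drive <- c(numeric(nb), rep(1, n - nb))
  env_phase <- narrowband_phase(env_rec, fs,
                                max(0.2, spec$rate_hz - 0.5),
                                spec$rate_hz + 0.5)
  envb <- envelope_band_component(env_full, fs, spec$rate_hz, sp$env_delay_s)
  chans <- c("audL", "audR", "frontal")
  data <- array(0, dim = c(n_trials, length(chans), n),
                dimnames = list(NULL, chans, NULL))
  for (j in seq_len(n_trials)) {
    sj <- derive_seed(sp$seed, j)
    oscR <- simulate_entrained_oscillator(env_phase, sp$right_osc, fs,
                                          seed = derive_seed(sj, 1L),
                                          drive = drive)
    oscL <- simulate_entrained_oscillator(env_phase, sp$left_osc, fs,
                                          seed = derive_seed(sj, 2L),
                                          drive = drive)
    noise <- with_seed(derive_seed(sj, 3L),
                       matrix(rnorm(3L * n, sd = sp$noise_amp), nrow = 3L))
    lag_j <- max(0, sp$frontal_lag_s +
                   with_seed(derive_seed(sj, 4L),
                             rnorm(1, sd = sp$frontal_jitter_s)))
    envb_frontal <- delay_samples(envb, lag_j * fs)
    data[j, "audL", ] <- sp$w_left * oscL$signal + sp$g_td * envb + noise[1, ]
    data[j, "audR", ] <- oscR$signal + noise[2, ]
    data[j, "frontal", ] <- sp$c_frontal * envb_frontal + noise[3, ]
  }
  structure(list(data = data, channel_names = chans, fs_hz = fs,
                 stimulus = stim, envelope_rec = env_rec,
                 condition = condition,
                 baseline_s = baseline_s, truth = sp),
            class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<simulated_recording> %d trials x %d channels x %d samples at %g Hz (condition '%s', rate %g /s)\n",
    d[1], d[2], d[3], x$fs_hz, x$condition, x$stimulus$rate_hz))
  invisible(x)
}

#' Draw per-subject generative parameters for a cohort
#'
#' The top-down gain is drawn `g_td ~ Uniform(g_range[1], g_range[2])` and
#' the frontal coupling is tied to it with mixing weight `rho`:
#' `c_frontal = rho * g_td / max(g_range) + (1 - rho) * Uniform(0, 1)`, so
#' `rho = 1` makes frontal coupling and top-down gain rank-identical and
#' `rho = 0` makes them independent. Oscillator natural frequencies and
#' couplings get mild inter-subject jitter around the defaults.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param seed master seed; subject `k` uses `derive_seed(seed, k)`.
#' @param g_range range of the top-down gain (default `c(0, 0.4)`).
#' @param rho gain--frontal coupling correlation weight in `[0, 1]`.
#' @param c_max upper bound of the frontal coupling `c_frontal`; the drawn
#'   mixture is scaled into `[0, c_max]`.
#' @param f_nat_right_hz,K_right,sigma_right right-oscillator defaults.
#' @param f_nat_left_hz,K_left,sigma_left left-oscillator defaults.
#' @param noise_amp measurement-noise SD.
#' @param w_left left intrinsic amplitude.
#' @param frontal_lag_s frontal lag, seconds.
#' @return list of [subject_params()] with a `truth` attribute: a data.frame
#'   `subject_id, g_td, c_frontal, K_left, K_right, f_nat_left, f_nat_right,
#'   seed`.
#' @export
sample_subject_params <- function(n_subjects, seed,
                                  g_range = c(0, 0.4), rho = 0.8,
                                  c_max = 0.25,
                                  f_nat_right_hz = 4.6,
                                  K_right = 2 * pi * 0.8,
                                  sigma_right = 0.7,
                                  f_nat_left_hz = 4.5, K_left = 0,
                                  sigma_left = 1.2,
                                  noise_amp = 1.3, w_left = 0.05,
                                  frontal_lag_s = 0.05) {
  if (n_subjects < 3) stop("n_subjects must be >= 3 (cohort statistics undefined below that)")
  g_max <- max(g_range)
  subjects <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    sk <- derive_seed(seed, k)
    subjects[[k]] <- with_seed(sk, {
      g_td <- runif(1, g_range[1], g_range[2])
      c_frontal <- c_max * min(1, max(0, rho * g_td / max(g_max, 1e-12) +
                                        (1 - rho) * runif(1)))
      fR <- f_nat_right_hz + rnorm(1, sd = 0.15)
      fL <- f_nat_left_hz + runif(1, -1.5, 1.5)
      kR <- K_right * exp(rnorm(1, sd = 0.05))
      subject_params(
        right_osc = oscillator_params(fR, kR, sigma_right,
                                      phi0 = runif(1, 0, 2 * pi)),
        left_osc = oscillator_params(fL, K_left, sigma_left,
                                     phi0 = runif(1, 0, 2 * pi)),
        g_td = g_td, c_frontal = c_frontal,
        frontal_lag_s = frontal_lag_s, noise_amp = noise_amp,
        seed = derive_seed(sk, 0L), w_left = w_left)
    })
    p <- subjects[[k]]
    truth[[k]] <- data.frame(
      subject_id = k, g_td = p$g_td, c_frontal = p$c_frontal,
      K_left = p$left_osc$K, K_right = p$right_osc$K,
      f_nat_left = p$left_osc$f_nat_hz, f_nat_right = p$right_osc$f_nat_hz,
      seed = p$seed)
  }
  attr(subjects, "truth") <- do.call(rbind, truth)
  subjects
}

#' Simulate a full cohort of recordings
#'
#' Convenience wrapper: [sample_subject_params()] then [simulate_subject()]
#' for each subject under one stimulus spec.
#'
#' @inheritParams sample_subject_params
#' @param spec a [stimulus_spec()].
#' @param n_trials trials per subject.
#' @param baseline_s silent baseline per trial, seconds.
#' @param ... further arguments passed to [sample_subject_params()].
#' @return list with `recordings` (list of `simulated_recording`) and
#'   `truth` (data.frame of generating parameters).
#' @export
simulate_cohort <- function(n_subjects, spec, n_trials, seed,
                            baseline_s = 0, ...) {
  params <- sample_subject_params(n_subjects, seed, ...)
  recs <- lapply(params, simulate_subject, spec = spec, n_trials = n_trials,
                 baseline_s = baseline_s)
  list(recordings = recs, truth = attr(params, "truth"))
}
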