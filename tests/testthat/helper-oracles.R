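# Independent oracles used across the suite. These deliberately avoid the
# package's own windowing/averaging code paths.

# Brute-force windowed PLV: band-limited phase extraction, then explicit
# loops over half-open windows [start, start + window) at stride
# (window - overlap), dropping the trailing partial window; direct phasor
# sum per window; plain mean.
oracle_windowed_plv <- function(brain, env, fs, f_lo, f_hi, window_s,
                                overlap_s) {
  ph1 <- narrowband_phase(brain, fs, f_lo, f_hi)$values
  ph2 <- narrowband_phase(env, fs, f_lo, f_hi)$values
  L <- length(brain) / fs
  stride <- window_s - overlap_s
  vals <- c()
  s0 <- 0
  while (s0 + window_s <= L + 1e-9) {
    i0 <- round(s0 * fs) + 1L
    idx <- i0:(i0 + round(window_s * fs) - 1L)
    acc <- 0 + 0i
    for (i in idx) acc <- acc + exp(1i * (ph1[i] - ph2[i]))
    vals <- c(vals, Mod(acc) / length(idx))
    s0 <- s0 + stride
  }
  mean(vals)
}

# Reference integration of the forced phase oscillator at a 10x finer step
# (plain Euler, no noise), independent of the package integrator.
oracle_adler_phase <- function(f_nat, K, f_stim, duration_s, fs, phi0 = 0) {
  fine <- 10 * fs
  n <- round(duration_s * fine)
  dt <- 1 / fine
  th <- numeric(n)
  th[1] <- phi0
  for (t in 2:n) {
    th_env <- 2 * pi * f_stim * (t - 2) * dt
    th[t] <- th[t - 1] + (2 * pi * f_nat + K * sin(th_env - th[t - 1])) * dt
  }
  th[seq(1, n, by = 10)]
}

# One-sided amplitude spectrum; returns data.frame(freq, amp).
oracle_spectrum <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[1:(n %/% 2)]
  data.frame(freq = (seq_len(n %/% 2) - 1) * fs / n, amp = sp)
}

make_tone <- function(f, duration_s, fs, phase = 0)
  cos(2 * pi * f * seq(0, duration_s - 1 / fs, by = 1 / fs) + phase)
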