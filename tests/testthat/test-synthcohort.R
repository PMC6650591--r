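test_that("syllable streams have the forced onset count and a unit-peak nonnegative envelope", {
  st <- make_syllable_stream(stimulus_spec(4.5, 2, 200))
  expect_length(st$onset_times_s, 9L)
  expect_equal(diff(st$onset_times_s), rep(1 / 4.5, 8))

  st2 <- make_syllable_stream(stimulus_spec(2.5, 6, 200))
  expect_length(st2$onset_times_s, 15L)
  expect_true(all(st2$envelope >= 0))
  expect_equal(max(st2$envelope), 1)
})

test_that("invalid stimulus specs are rejected with the violated invariant named", {
  expect_error(stimulus_spec(4.5, 2, 200, syllable_dur_s = 0.5),
               "overlapping")
  expect_error(stimulus_spec(4.5, 0.3, 200), "two syllable periods")
  expect_error(stimulus_spec(50, 2, 100), "4 \\* rate_hz")
})

test_that("am_noise carrier's extracted envelope has its modulation peak at the syllable rate", {
  spec <- stimulus_spec(4.5, 4, 16000, carrier = "am_noise", seed = 7)
  st <- make_syllable_stream(spec)
  env <- multiband_envelope(st$audio, 16000)
  sp <- oracle_spectrum(env$values, env$fs_hz)
  sel <- sp$freq > 1 & sp$freq < 10
  peak <- sp$freq[sel][which.max(sp$amp[sel])]
  expect_lt(abs(peak - 4.5), 1 / 4 + 1e-9)  # within one bin of a 4 s record
})

test_that("noiseless forced oscillator locks at zero detuning and at the Adler fixed-point lag", {
  fs <- 200
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  env_phase <- 2 * pi * 4.5 * t
  post <- (5 * fs):length(t)

  osc <- simulate_entrained_oscillator(env_phase,
                                       oscillator_params(4.5, K = 2 * pi * 1.5),
                                       fs)
  expect_gt(plv(osc$phase$values[post], wrap_phase(env_phase[post])), 0.999)

  # detuning 1 Hz, K = 2*pi*1.5: locked lag asin(1/1.5)
  osc2 <- simulate_entrained_oscillator(env_phase,
                                        oscillator_params(3.5, K = 2 * pi * 1.5),
                                        fs)
  lag <- mean(wrap_phase(env_phase[post] - osc2$phase$unwrapped[post]))
  expect_lt(abs(lag - asin(1 / 1.5)), 0.01)
})

test_that("outside the Arnold tongue the phase drifts, matching a finer-step reference integration", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  env_phase <- 2 * pi * 4.5 * t
  post <- (5 * fs):length(t)
  osc <- simulate_entrained_oscillator(env_phase,
                                       oscillator_params(3.5, K = 2 * pi * 0.5),
                                       fs)
  expect_lt(plv(osc$phase$values[post], wrap_phase(env_phase[post])), 0.9)
  ref <- oracle_adler_phase(3.5, 2 * pi * 0.5, 4.5, 60, fs)
  expect_lt(plv(osc$phase$values[post], wrap_phase(env_phase[post])) -
              plv(wrap_phase(ref[post]), wrap_phase(env_phase[post])), 0.05)
})

test_that("identical seeds give bit-identical recordings and truth tables", {
  sp <- subject_params(oscillator_params(4.75, 2 * pi * 0.8, 0.5, 1),
                       oscillator_params(4.5, 0, 1, 2),
                       g_td = 0.3, c_frontal = 0.2, seed = 99)
  spec <- stimulus_spec(4.5, 3, 200)
  r1 <- simulate_subject(sp, spec, 2)
  r2 <- simulate_subject(sp, spec, 2)
  expect_identical(r1$data, r2$data)

  p1 <- sample_subject_params(5, seed = 123)
  p2 <- sample_subject_params(5, seed = 123)
  expect_identical(attr(p1, "truth"), attr(p2, "truth"))
  expect_false(identical(attr(p1, "truth"),
                         attr(sample_subject_params(5, seed = 124), "truth")))
})

test_that("noise-free symmetric subject has exactly zero asymmetry", {
  # identical oscillators (sigma = 0 so the seeds are irrelevant), w_left = 1,
  # no top-down component, no noise: left and right channels coincide.
  osc <- oscillator_params(4.6, K = 2 * pi * 0.8, sigma = 0, phi0 = 0.5)
  sp <- subject_params(osc, osc, g_td = 0, c_frontal = 0, noise_amp = 0,
                       w_left = 1, seed = 5)
  rec <- simulate_subject(sp, stimulus_spec(4.5, 6, 200), 2)
  expect_equal(rec$data[, "audL", ], rec$data[, "audR", ])
  l <- windowed_plv(rec$data[1, "audL", ], rec$envelope_rec, 200,
                    c(4, 5), 2, 1)$value
  r <- windowed_plv(rec$data[1, "audR", ], rec$envelope_rec, 200,
                    c(4, 5), 2, 1)$value
  expect_identical(asymmetry_index(r, l)$value, 0)
})

test_that("rho = 1 cohorts make frontal coupling rank-identical to the top-down gain", {
  p <- sample_subject_params(12, seed = 3, rho = 1, g_range = c(0, 2))
  tr <- attr(p, "truth")
  expect_identical(order(tr$g_td), order(tr$c_frontal))
  expect_error(sample_subject_params(2, seed = 1), "n_subjects")
})

test_that("per-hemisphere entrainment profile: right is rate-tuned, envelope-driven left is flat", {
  # 6-replicate average at three rates; right PLV peaks at the natural
  # frequency, left (pure top-down) spread below 0.1 across rates
  rates <- c(2.5, 4.5, 6.5)
  right <- matrix(NA_real_, 6, length(rates))
  left <- matrix(NA_real_, 6, length(rates))
  for (i in 1:6) {
    for (j in seq_along(rates)) {
      sp <- subject_params(
        oscillator_params(4.75, K = 2 * pi * 0.8, sigma = 0.7, phi0 = i),
        oscillator_params(4.5, 0, 1.2, i), g_td = 0.6, c_frontal = 0.1,
        noise_amp = 1, w_left = 0.1, seed = 40 + i)
      rec <- simulate_subject(sp, stimulus_spec(rates[j], 8, 200,
                                                seed = derive_seed(7, j)), 2)
      band <- c(rates[j] - 0.5, rates[j] + 0.5)
      right[i, j] <- windowed_plv(rec$data[1, "audR", ], rec$envelope_rec,
                                  200, band, 2, 1)$value
      left[i, j] <- windowed_plv(rec$data[1, "audL", ], rec$envelope_rec,
                                 200, band, 2, 1)$value
    }
  }
  r_mean <- colMeans(right)
  expect_equal(which.max(r_mean), 2L)  # peak at 4.5, within 1 Hz of f_nat
  expect_lt(max(colMeans(left)) - min(colMeans(left)), 0.1)
})
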