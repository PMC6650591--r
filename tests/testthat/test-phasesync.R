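test_that("plv analytic values: constant lag, alternating quarter-turn, cancellation", {
  th <- runif(50, -pi, pi)
  expect_equal(plv(th, th - 1.3), 1.0)
  expect_equal(plv(rep(c(0, pi / 2), 50), numeric(100)), sqrt(2) / 2)
  expect_equal(plv(rep(c(0, pi), 50), numeric(100)), 0)
  expect_error(plv(1:3, 1:4), "lengths")
  expect_error(plv(1, 1), "T = 2")
})

test_that("plv is invariant to a common phase offset and bounded in [0, 1]", {
  set.seed(1)
  for (i in 1:20) {
    a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
    v <- plv(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(plv(a + 0.7, b + 0.7), v)
  }
})

test_that("windowed_plv tiles half-open windows and matches the brute-force oracle", {
  fs <- 200
  x <- make_tone(4.5, 6, fs)
  wp <- windowed_plv(x, x, fs, c(4, 5), 2, 1)
  expect_identical(wp$n_windows, 5L)
  expect_gt(wp$value, 0.999)

  set.seed(11)
  for (i in 1:10) {
    n <- sample(800:1600, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- windowed_plv(a, b, fs, c(3.5, 5.5), 1, 0.5)$value
    want <- oracle_windowed_plv(a, b, fs, 3.5, 5.5, 1, 0.5)
    expect_lt(abs(got - want), 1e-12)
  }
})

test_that("windowed_plv validates overlap and window coverage", {
  x <- rnorm(600)
  expect_error(windowed_plv(x, x, 200, c(3.5, 5.5), 1, 1), "overlap_s")
  expect_error(windowed_plv(x, x, 200, c(3.5, 5.5), 4, 1), "window")
})

test_that("percent change from baseline evaluates directly and rejects zero baseline", {
  expect_equal(percent_change(0.5, 0.25), 1)
  expect_equal(percent_change(0.3, 0.3), 0)
  expect_equal(percent_change(0.1, 0.4), -0.75)
  expect_error(percent_change(0.5, 0), "plv_base")
})

test_that("asymmetry index: direct values, antisymmetry, bounds at zero arguments", {
  expect_equal(asymmetry_index(0.3, 0.3)$value, 0)
  expect_equal(asymmetry_index(0.6, 0.2)$value, 1)
  expect_equal(asymmetry_index(0.2, 0.6)$value, -1)
  expect_equal(asymmetry_index(0.4, 0)$value, 2)
  set.seed(2)
  for (i in 1:25) {
    a <- runif(1); b <- runif(1)
    ai <- asymmetry_index(a, b)$value
    expect_equal(ai, -asymmetry_index(b, a)$value)
    expect_lte(abs(ai), 2)
  }
  expect_error(asymmetry_index(0, 0), "both")
})

test_that("trial coherence: self-coherence is 1, a common lag leaves tonal coherence at 1", {
  fs <- 100
  set.seed(3)
  tr <- matrix(rnorm(6 * 200), nrow = 6)
  expect_equal(coherence_at_freq(tr, tr, fs, 10)$value, 1)

  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- t(sapply(1:5, function(i) cos(2 * pi * 10 * t + i)))
  y <- t(sapply(1:5, function(i) cos(2 * pi * 10 * t + i - 0.9)))
  expect_gt(coherence_at_freq(x, y, fs, 10)$value, 0.999)
  expect_error(coherence_at_freq(tr[1, , drop = FALSE],
                                 tr[1, , drop = FALSE], fs, 10), "2 trials")
})

test_that("coherence is invariant to per-trial amplitude scaling of one side, Fisher z monotone", {
  fs <- 100
  set.seed(4)
  x <- matrix(rnorm(8 * 300), nrow = 8)
  y <- matrix(rnorm(8 * 300), nrow = 8) + 0.5 * x
  c0 <- coherence_at_freq(x, y, fs, 10)
  c1 <- coherence_at_freq(2.7 * x, y, fs, 10)  # common scale on one side
  expect_equal(c1$value, c0$value, tolerance = 1e-10)
  c_lo <- coherence_at_freq(matrix(rnorm(8 * 300), nrow = 8), y, fs, 10)
  expect_equal(c0$fisher_z, atanh(c0$value))
  expect_true((c0$value - c_lo$value) * (c0$fisher_z - c_lo$fisher_z) >= 0)
})

test_that("roi_average is the mean over the mask and rejects empty masks", {
  expect_equal(roi_average(c(0.2, 0.4), c(TRUE, TRUE)), 0.3)
  expect_equal(roi_average(c(0.2, 0.4, 0.9), 2), 0.4)
  v <- runif(10)
  expect_lte(roi_average(v, 1:5), max(v[1:5]))
  expect_error(roi_average(v, logical(10)), "no units")
})
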