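test_that("Morlet response to a tone: flat interior magnitude, correct phase slope, linearity", {
  fs <- 200
  x <- make_tone(4.5, 30, fs)
  m <- morlet_coefficients(x, fs, 4.5, 9)
  interior <- which(!m$edge)
  mag <- Mod(m$coeffs[interior])
  expect_lt(diff(range(mag)) / mean(mag), 0.01)
  ph <- Arg(m$coeffs[interior])
  slopes <- wrap_phase(diff(ph)) * fs / (2 * pi)
  expect_lt(abs(mean(slopes) - 4.5) / 4.5, 0.001)

  m5 <- morlet_coefficients(5 * x, fs, 4.5, 9)
  expect_equal(m5$coeffs, 5 * m$coeffs, tolerance = 1e-10)
})

test_that("Morlet magnitude ratio across tones follows the Gaussian frequency response", {
  fs <- 200
  m45 <- morlet_coefficients(make_tone(4.5, 40, fs), fs, 4.5, 9)
  m60 <- morlet_coefficients(make_tone(6.0, 40, fs), fs, 4.5, 9)
  ratio <- mean(Mod(m60$coeffs[!m60$edge])) / mean(Mod(m45$coeffs[!m45$edge]))
  sigma_f <- 4.5 / 9           # spectral SD of the wavelet
  want <- exp(-(6 - 4.5)^2 / (2 * sigma_f^2))
  expect_lt(abs(ratio - want) / want, 0.05)
})

test_that("wPLI square estimator boundary values and volume-conduction immunity", {
  set.seed(5)
  # constant +90 deg lag with arbitrary amplitudes -> exactly 1
  zy <- exp(1i * runif(100, -pi, pi)) * runif(100, 0.2, 3)
  zx <- zy * 1i * runif(100, 0.5, 2)
  expect_equal(wpli_square_time(zx, zy), 1, ignore_attr = TRUE)

  # purely real cross-spectrum (zero lag) -> 0 with the degenerate flag
  zr <- complex(real = rnorm(50))
  v <- wpli_square_time(zr, zr * runif(50, 0.5, 2))
  expect_identical(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))

  # Y = {+1, -1} at T = 2 -> (0 - 2) / (4 - 2) = -1
  expect_equal(wpli_square_time(c(1 + 0i, 1 + 0i), c(-1i, 1i)), -1,
               ignore_attr = TRUE)
  expect_error(wpli_square_time(1 + 0i, 2 + 0i), "2 usable")
})

test_that("wPLI estimators are symmetric under channel swap and amplitude-invariant", {
  set.seed(6)
  for (i in 1:10) {
    zx <- complex(real = rnorm(200), imaginary = rnorm(200))
    zy <- complex(real = rnorm(200), imaginary = rnorm(200)) + 0.4 * zx
    expect_equal(wpli_square_time(zx, zy), wpli_square_time(zy, zx))
    expect_equal(wpli_square_time(3.7 * zx, zy), wpli_square_time(zx, zy),
                 tolerance = 1e-12)
    expect_equal(dwpli_trials(zx, zy), dwpli_trials(zy, zx))
  }
})

test_that("dwPLI across trials: boundaries and degenerate input", {
  zy <- exp(1i * seq(0.1, 2, length.out = 20))
  expect_equal(dwpli_trials(zy * 1i, zy), 1, ignore_attr = TRUE)
  v <- dwpli_trials(complex(real = 1:10), complex(real = 2:11))
  expect_identical(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))
  expect_error(dwpli_trials(1i, 2i), "2 trials")
})

test_that("both estimators stay within [-1, 1] on random coefficient streams", {
  set.seed(7)
  for (i in 1:20) {
    zx <- complex(real = rnorm(60), imaginary = rnorm(60))
    zy <- complex(real = rnorm(60), imaginary = rnorm(60))
    expect_lte(abs(wpli_square_time(zx, zy)), 1)
    expect_lte(abs(dwpli_trials(zx, zy)), 1)
  }
})

test_that("ROI-pair connectivity averages between regions and zeroes self-connectivity", {
  m <- matrix(c(0.9, 0.4, 0.4, 0.8), 2, 2)
  expect_equal(roi_pair_connectivity(m, 1, 2), 0.4)
  expect_equal(roi_pair_connectivity(m, 1, 1), 0)
  u <- matrix(0.3, 4, 4)
  expect_equal(roi_pair_connectivity(u, 1:2, 3:4), 0.3)
  expect_error(roi_pair_connectivity(m, integer(0), 1), "empty")
})
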