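#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing used throughout the package so that subject
#' `k` of a cohort, and trial `j` of a subject, get reproducible independent
#' RNG streams from one master seed. The mapping is a fixed Lehmer-style
#' multiplicative mix modulo 2^31 - 1 and is stable across package versions.
#'
#' @param seed integer master seed.
#' @param k nonnegative integer index (subject, trial, ...).
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, k) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271) %% m
  x <- (x + as.numeric(k) + 1) %% m
  x <- (x * 48271) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 2) + 1)
}

# Evaluate expr with a local RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal of a real series (the Hilbert
#' construction): positive frequencies doubled, negative zeroed.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < 2L) stop("analytic_signal: need at least 2 samples")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(theta) {
  v <- (theta + pi) %% (2 * pi) - pi
  v[v <= -pi] <- v[v <= -pi] + 2 * pi
  v
}

# Zero-phase Butterworth band-pass (order `order`, applied forward-backward).
bandpass_zerophase <- function(x, fs_hz, f_lo, f_hi, order = 4) {
  if (!(f_lo > 0 && f_hi > f_lo && f_hi < fs_hz / 2))
    stop(sprintf("band [%g, %g] Hz invalid for fs = %g Hz (need 0 < f_lo < f_hi < fs/2)",
                 f_lo, f_hi, fs_hz))
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs_hz / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# Delay a series by an integer number of samples, zero-padding the head.
delay_samples <- function(x, d) {
  d <- as.integer(round(d))
  if (d <= 0L) return(x)
  n <- length(x)
  if (d >= n) return(numeric(n))
  c(numeric(d), x[1:(n - d)])
}
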