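#' Instantaneous phase of a band-limited signal
#'
#' Zero-phase band-pass (Butterworth order 4, applied forward-backward with
#' `filtfilt`) followed by the analytic-signal angle. The returned phase is
#' wrapped to `(-pi, pi]`; an `edge` logical marks the first and last
#' `edge_s` seconds, which are distorted by filter transients and should be
#' excluded from phase-locking windows when precision matters.
#'
#' @param x real series.
#' @param fs_hz sampling rate.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < fs_hz / 2`.
#' @param edge_s edge span flagged on each side, seconds.
#' @return a `phase_series`: list with `values` (wrapped radians), `fs_hz`,
#'   `edge` (logical mask) and `unwrapped`.
#' @export
narrowband_phase <- function(x, fs_hz, f_lo, f_hi, edge_s = 0.5) {
  n <- length(x)
  if (n / fs_hz * f_lo < 3)
    stop(sprintf("series too short: fewer than 3 cycles of f_lo = %g Hz", f_lo))
  xb <- bandpass_zerophase(x, fs_hz, f_lo, f_hi)
  z <- analytic_signal(xb)
  ph <- Arg(z)
  # continuous (unwrapped) view for slope/lag computations
  dph <- wrap_phase(diff(ph))
  unwrapped <- cumsum(c(ph[1], dph))
  ne <- min(n, round(edge_s * fs_hz))
  edge <- rep(FALSE, n)
  if (ne > 0) edge[c(seq_len(ne), n - seq_len(ne) + 1L)] <- TRUE
  phase_series(wrap_phase(ph), fs_hz, edge = edge, unwrapped = unwrapped)
}

#' Construct a phase series
#'
#' @param values phase values in radians; wrapped into `(-pi, pi]`.
#' @param fs_hz sampling rate.
#' @param edge optional logical mask of edge-distorted samples.
#' @param unwrapped optional continuous phase of the same length.
#' @return object of class `phase_series`.
#' @export
phase_series <- function(values, fs_hz, edge = NULL, unwrapped = NULL) {
  stopifnot(is.numeric(values), all(is.finite(values)), fs_hz > 0)
  structure(list(values = wrap_phase(values), fs_hz = fs_hz,
                 edge = edge %||% rep(FALSE, length(values)),
                 unwrapped = unwrapped),
            class = "phase_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples at %g Hz (%.3g s), %d edge-flagged\n",
              length(x$values), x$fs_hz, length(x$values) / x$fs_hz,
              sum(x$edge)))
  invisible(x)
}

# ERB-rate scale (Glasberg & Moore): number-of-ERBs as a function of Hz,
# and its inverse, used to space the cochlear filterbank edges.
hz_to_erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Cochlear-style multiband speech envelope
#'
#' Filters the waveform into `n_bands` bands with edges equally spaced on
#' the ERB-rate scale between `f_min` and `min(f_max, 0.45 * fs_hz)`
#' (zero-phase Butterworth order 4), takes the analytic-signal magnitude in
#' each band, averages the magnitudes across bands, then anti-alias filters
#' (low-pass 200 Hz) and polyphase-resamples to `out_fs_hz`.
#'
#' @param audio real waveform.
#' @param fs_hz input sampling rate; must exceed twice the top band edge.
#' @param n_bands number of filterbank bands (default 8).
#' @param f_min,f_max filterbank frequency range, Hz (defaults 100, 8000).
#' @param out_fs_hz output envelope sampling rate (default 500).
#' @return an `envelope_series`: list with nonnegative `values` at
#'   `fs_hz = out_fs_hz`, plus a `params` provenance list.
#' @export
multiband_envelope <- function(audio, fs_hz, n_bands = 8,
                               f_min = 100, f_max = 8000, out_fs_hz = 500) {
  top <- min(f_max, 0.45 * fs_hz)
  if (top <= f_min)
    stop(sprintf("fs_hz = %g too low: top band edge %g Hz <= f_min %g Hz",
                 fs_hz, top, f_min))
  edges <- erb_to_hz(seq(hz_to_erb(f_min), hz_to_erb(top),
                         length.out = n_bands + 1L))
  if (2 * max(edges) > fs_hz)
    stop(sprintf("band %g-%g Hz violates Nyquist at fs = %g Hz",
                 edges[n_bands], edges[n_bands + 1L], fs_hz))
  if (length(audio) < 10 * fs_hz / f_min)
    stop("audio too short for the filterbank impulse responses")
  acc <- numeric(length(audio))
  for (b in seq_len(n_bands)) {
    xb <- bandpass_zerophase(audio, fs_hz, edges[b], edges[b + 1L])
    acc <- acc + Mod(analytic_signal(xb))
  }
  env <- acc / n_bands
  if (out_fs_hz < fs_hz) {
    lp <- signal::butter(4, min(200, 0.8 * out_fs_hz / 2) / (fs_hz / 2),
                         type = "low")
    env <- signal::filtfilt(lp, env)
    frac <- ratio_integers(out_fs_hz, fs_hz)
    env <- signal::resample(env, frac[1], frac[2])
  }
  structure(list(values = pmax(env, 0), fs_hz = out_fs_hz,
                 params = list(n_bands = n_bands, edges_hz = edges,
                               filter = "butterworth order 4, zero-phase",
                               antialias_hz = min(200, 0.8 * out_fs_hz / 2),
                               in_fs_hz = fs_hz)),
            class = "envelope_series")
}

# Reduce p/q to smallest integers with p/q == a/b.
ratio_integers <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  scale <- 1
  while (abs(a * scale - round(a * scale)) > 1e-9 ||
         abs(b * scale - round(b * scale)) > 1e-9) scale <- scale * 10
  p <- round(a * scale); q <- round(b * scale)
  d <- g(p, q)
  c(p / d, q / d)
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d samples at %g Hz (%.3g s)\n",
              length(x$values), x$fs_hz, length(x$values) / x$fs_hz))
  invisible(x)
}
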