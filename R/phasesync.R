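#' Phase-locking value between two phase series
#'
#' `PLV = (1/T) |sum_t exp(i (theta1(t) - theta2(t)))|`: the modulus of the
#' time-averaged unit phasor of the phase difference. 1 means a constant
#' phase relation, 0 uniform scatter.
#'
#' @param theta1,theta2 `phase_series` objects or numeric radians of equal
#'   length `T >= 2` (and equal sampling rate if both are `phase_series`).
#' @return a number in `[0, 1]`.
#' @export
plv <- function(theta1, theta2) {
  t1 <- if (inherits(theta1, "phase_series")) theta1$values else theta1
  t2 <- if (inherits(theta2, "phase_series")) theta2$values else theta2
  if (inherits(theta1, "phase_series") && inherits(theta2, "phase_series") &&
      theta1$fs_hz != theta2$fs_hz)
    stop("phase series have different sampling rates")
  if (length(t1) != length(t2)) stop("phase series lengths differ")
  if (length(t1) < 2) stop("need at least T = 2 time points")
  Mod(mean(exp(1i * (t1 - t2))))
}

#' Windowed band-limited PLV between a signal and the stimulus envelope
#'
#' Both series are reduced to narrowband instantaneous phase
#' ([narrowband_phase()]) in `band`, the segment is tiled with half-open
#' windows `[start, start + window_s)` at stride `window_s - overlap_s`
#' (trailing partial window dropped), the PLV is computed per window, and
#' the window PLVs are averaged.
#'
#' @param brain,env real series of equal length.
#' @param fs_hz sampling rate.
#' @param band numeric length-2, `c(f_lo, f_hi)` in Hz.
#' @param window_s window length, seconds.
#' @param overlap_s window overlap, seconds (`0 <= overlap_s < window_s`).
#' @return object of class `plv_result`: `value` (mean PLV), `n_windows`,
#'   `per_window`, `band_hz`, `window_s`, `overlap_s`.
#' @export
windowed_plv <- function(brain, env, fs_hz, band, window_s, overlap_s) {
  if (length(brain) != length(env)) stop("brain and env lengths differ")
  if (!(overlap_s >= 0 && overlap_s < window_s))
    stop("need 0 <= overlap_s < window_s")
  L <- length(brain) / fs_hz
  if (L < window_s) stop("series shorter than one window")
  ph_b <- narrowband_phase(brain, fs_hz, band[1], band[2])
  ph_e <- narrowband_phase(env, fs_hz, band[1], band[2])
  starts <- window_starts(L, window_s, overlap_s)
  if (length(starts) == 0) stop("zero usable windows")
  wn <- round(window_s * fs_hz)
  per <- vapply(starts, function(s0) {
    i0 <- round(s0 * fs_hz) + 1L
    idx <- i0:(i0 + wn - 1L)
    plv(ph_b$values[idx], ph_e$values[idx])
  }, numeric(1))
  structure(list(value = mean(per), n_windows = length(per),
                 per_window = per, band_hz = band,
                 window_s = window_s, overlap_s = overlap_s),
            class = "plv_result")
}

# Half-open window tiling of [0, L): starts at stride window - overlap while
# the full window fits (float tolerance 1e-9 s).
window_starts <- function(L, window_s, overlap_s) {
  stride <- window_s - overlap_s
  starts <- seq(0, L, by = stride)
  starts[starts + window_s <= L + 1e-9]
}

#' @export
print.plv_result <- function(x, ...) {
  cat(sprintf("<plv_result> PLV = %.4f over %d windows (%g-%g Hz, %g s / %g s overlap)\n",
              x$value, x$n_windows, x$band_hz[1], x$band_hz[2],
              x$window_s, x$overlap_s))
  invisible(x)
}

#' Percent change of synchronization from baseline
#'
#' `(plv_stim - plv_base) / plv_base`.
#'
#' @param plv_stim PLV in the stimulation window.
#' @param plv_base PLV in the baseline window (> 0).
#' @return signed fractional change.
#' @export
percent_change <- function(plv_stim, plv_base) {
  if (!is.finite(plv_base) || plv_base <= 0)
    stop("plv_base must be > 0 (percent change undefined)")
  (plv_stim - plv_base) / plv_base
}

#' Hemispheric asymmetry index
#'
#' `2 (plv_right - plv_left) / (plv_right + plv_left)`: positive values
#' indicate rightward dominance; bounded in `[-2, 2]` with the bounds
#' attained only when one hemisphere's value is zero. Antisymmetric under
#' swapping hemispheres.
#'
#' @param plv_right,plv_left nonnegative synchronization values, not both 0.
#' @return object of class `asymmetry_index` with fields `value`,
#'   `plv_right`, `plv_left`.
#' @export
asymmetry_index <- function(plv_right, plv_left) {
  if (plv_right < 0 || plv_left < 0)
    stop("synchronization values must be nonnegative")
  if (plv_right + plv_left <= 0)
    stop("asymmetry undefined when both values are zero")
  structure(list(value = 2 * (plv_right - plv_left) / (plv_right + plv_left),
                 plv_right = plv_right, plv_left = plv_left),
            class = "asymmetry_index")
}

#' @export
print.asymmetry_index <- function(x, ...) {
  cat(sprintf("<asymmetry_index> %.4f (right %.4f, left %.4f)\n",
              x$value, x$plv_right, x$plv_left))
  invisible(x)
}

# Hann-tapered complex spectral coefficient of each trial at the FFT bin
# nearest f0. trials: matrix (rows = trials) or list of equal-length series.
trial_coefficients <- function(trials, fs_hz, f0_hz) {
  if (is.list(trials)) trials <- do.call(rbind, trials)
  if (is.vector(trials)) trials <- matrix(trials, nrow = 1)
  N <- ncol(trials)
  k <- round(f0_hz * N / fs_hz)         # nearest DFT bin
  taper <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1)))
  basis <- exp(-2i * pi * k * (0:(N - 1)) / N)
  as.complex((trials * rep(taper, each = nrow(trials))) %*% basis)
}

#' Trial-wise spectral coherence at one frequency
#'
#' Per trial, a single-taper (Hann) complex spectral coefficient is taken at
#' the FFT bin nearest `f0_hz`; coherence across trials is
#' `|sum_i X_i conj(Y_i)|^2 / (sum_i |X_i|^2 * sum_i |Y_i|^2)`, with the
#' Fisher z transform `atanh(coherence)` attached. The frequency resolution
#' is `fs_hz / N` for trial length `N`; a warning is raised when the nearest
#' bin is further than half a resolution step from `f0_hz`.
#'
#' @param trials_x,trials_y per-trial real series: matrices with one row per
#'   trial, or lists of equal-length vectors. At least 2 trials.
#' @param fs_hz sampling rate.
#' @param f0_hz target frequency.
#' @param resolution_hz optional expected resolution; checked against
#'   `fs_hz / N` when given.
#' @return object of class `coherence_result`: `value` in `[0, 1]`,
#'   `fisher_z`, `f0_hz`, `resolution_hz`, `n_trials`.
#' @export
coherence_at_freq <- function(trials_x, trials_y, fs_hz, f0_hz,
                              resolution_hz = NULL) {
  X <- trial_coefficients(trials_x, fs_hz, f0_hz)
  Y <- trial_coefficients(trials_y, fs_hz, f0_hz)
  if (length(X) != length(Y)) stop("trial counts differ")
  if (length(X) < 2) stop("trial-wise coherence needs at least 2 trials")
  N <- if (is.list(trials_x)) length(trials_x[[1]]) else ncol(as.matrix(trials_x))
  res <- fs_hz / N
  if (!is.null(resolution_hz) && abs(res - resolution_hz) > 0.05 * resolution_hz)
    warning(sprintf("trial length gives resolution %.4g Hz, not the requested %.4g Hz",
                    res, resolution_hz))
  k <- round(f0_hz * N / fs_hz)
  if (abs(k * res - f0_hz) > res / 2)
    warning(sprintf("nearest bin %.4g Hz is more than half a resolution step from f0 = %g Hz",
                    k * res, f0_hz))
  num <- Mod(sum(X * Conj(Y)))^2
  den <- sum(Mod(X)^2) * sum(Mod(Y)^2)
  value <- if (den > 0) min(1, num / den) else 0
  structure(list(value = value,
                 fisher_z = if (value < 1) atanh(value) else Inf,
                 f0_hz = f0_hz, resolution_hz = res,
                 n_trials = length(X)),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %.4f at %g Hz (res %.4g Hz, %d trials, Fisher z %.4f)\n",
              x$value, x$f0_hz, x$resolution_hz, x$n_trials, x$fisher_z))
  invisible(x)
}

#' Average a metric over a region of interest
#'
#' @param values per-unit (voxel/sensor) numeric values.
#' @param mask logical mask or integer indices selecting the ROI; nonempty.
#' @return arithmetic mean over the selected units.
#' @export
roi_average <- function(values, mask) {
  sel <- values[mask]
  if (length(sel) == 0) stop("ROI mask selects no units")
  mean(sel)
}
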