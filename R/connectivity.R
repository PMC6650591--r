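#' Complex Morlet wavelet coefficients at one center frequency
#'
#' Convolves the signal with a unit-energy complex Morlet kernel: Gaussian
#' temporal envelope of SD `n_cycles / (2 pi f0_hz)` carrying
#' `exp(i 2 pi f0_hz t)`, truncated at 3.5 SD. Samples within half a kernel
#' length of either edge are flagged and excluded from downstream wPLI sums.
#'
#' @param x real series, at least one kernel length long.
#' @param fs_hz sampling rate.
#' @param f0_hz center frequency (default 4.5 Hz).
#' @param n_cycles wavelet width in cycles (default 9, minimum 3).
#' @return object of class `spectral_coefficients` with complex `coeffs`,
#'   logical `edge`, and `f0_hz`, `n_cycles`, `fs_hz`, `mode = "wavelet"`.
#' @export
morlet_coefficients <- function(x, fs_hz, f0_hz = 4.5, n_cycles = 9) {
  if (n_cycles < 3) stop("n_cycles must be >= 3")
  sigma_t <- n_cycles / (2 * pi * f0_hz)
  half <- ceiling(3.5 * sigma_t * fs_hz)
  tt <- (-half:half) / fs_hz
  kern <- exp(-tt^2 / (2 * sigma_t^2)) * exp(1i * 2 * pi * f0_hz * tt)
  kern <- kern / sqrt(sum(Mod(kern)^2))
  n <- length(x)
  if (n < length(kern))
    stop(sprintf("series (%d samples) shorter than one wavelet (%d samples)",
                 n, length(kern)))
  # linear convolution via FFT, centered ("same")
  nfft <- stats::nextn(n + length(kern) - 1L, 2)
  z <- fft(fft(c(x, numeric(nfft - n))) *
             fft(c(kern, numeric(nfft - length(kern)))), inverse = TRUE) / nfft
  coeffs <- z[(half + 1L):(half + n)]
  edge <- rep(FALSE, n)
  edge[c(seq_len(min(n, half)), n - seq_len(min(n, half)) + 1L)] <- TRUE
  structure(list(coeffs = coeffs, edge = edge, f0_hz = f0_hz,
                 n_cycles = n_cycles, fs_hz = fs_hz, mode = "wavelet"),
            class = "spectral_coefficients")
}

#' @export
print.spectral_coefficients <- function(x, ...) {
  cat(sprintf("<spectral_coefficients> %s mode, %d points at %g Hz center (%s)\n",
              x$mode, length(x$coeffs), x$f0_hz,
              if (x$mode == "wavelet")
                sprintf("%g cycles, %d edge-flagged", x$n_cycles, sum(x$edge))
              else "per trial"))
  invisible(x)
}

# Pull complex coefficient vector + edge mask out of spectral_coefficients
# or a raw complex vector.
coef_values <- function(z) {
  if (inherits(z, "spectral_coefficients"))
    list(c = z$coeffs, edge = z$edge %||% rep(FALSE, length(z$coeffs)))
  else list(c = as.complex(z), edge = rep(FALSE, length(z)))
}

# Shared debiased-square form: (|sum w|^2 - sum w^2) / ((sum |w|)^2 - sum w^2)
# for a real weight series w; 0 with a degenerate flag when the denominator
# vanishes (e.g. all weights zero: purely zero-lag coupling).
debiased_square <- function(w) {
  s1 <- sum(w); s2 <- sum(w^2); sa <- sum(abs(w))
  den <- sa^2 - s2
  if (den <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure((s1^2 - s2) / den, degenerate = FALSE)
}

#' wPLI square estimator over wavelet time points
#'
#' Within-trial weighted phase lag index from two Morlet coefficient
#' series: the cross-spectrum `X_t = zx_t * conj(zy_t)` is reduced to its
#' normalized imaginary part `Y_t = Im(X_t) / |X_t|` (`Y_t = 0` where
#' `|X_t| = 0`) and the debiased square form
#' `(|sum Y|^2 - sum Y^2) / ((sum |Y|)^2 - sum Y^2)` is returned. Values
#' lie in `[-1, 1]`; 1 requires a constant-sign imaginary cross-spectrum;
#' zero-lag (volume-conducted) coupling yields 0 with a `degenerate`
#' attribute. Edge-flagged samples of either input are excluded.
#'
#' @param zx,zy `spectral_coefficients` (wavelet mode) or complex vectors of
#'   equal length; at least 2 usable time points.
#' @return number in `[-1, 1]` with logical attribute `degenerate`.
#' @export
wpli_square_time <- function(zx, zy) {
  a <- coef_values(zx); b <- coef_values(zy)
  if (length(a$c) != length(b$c)) stop("coefficient series lengths differ")
  keep <- !(a$edge | b$edge)
  X <- a$c[keep] * Conj(b$c[keep])
  if (length(X) < 2) stop("need at least 2 usable time points")
  m <- Mod(X)
  Y <- ifelse(m > 0, Im(X) / m, 0)
  debiased_square(Y)
}

#' Debiased wPLI across trials
#'
#' Trial-wise debiased weighted phase lag index: per trial the (unnormalized)
#' imaginary cross-spectrum `I_i = Im(zx_i * conj(zy_i))` is formed from the
#' per-trial spectral coefficients, then the same debiased square form as
#' [wpli_square_time()] is applied across trials.
#'
#' @param zx,zy complex vectors of per-trial coefficients (>= 2 trials).
#' @return number in `[-1, 1]` with logical attribute `degenerate`.
#' @export
dwpli_trials <- function(zx, zy) {
  zx <- as.complex(zx); zy <- as.complex(zy)
  if (length(zx) != length(zy)) stop("trial counts differ")
  if (length(zx) < 2) stop("need at least 2 trials")
  debiased_square(Im(zx * Conj(zy)))
}

#' Average connectivity between two regions of interest
#'
#' Mean of the connectivity-matrix entries between the units of `roi_a` and
#' `roi_b`. When the two ROIs are identical, self-connections (the diagonal)
#' are set to zero before averaging.
#'
#' @param matrix square unit-by-unit connectivity matrix.
#' @param roi_a,roi_b nonempty integer index vectors (or logical masks).
#' @return mean connectivity between the two ROIs.
#' @export
roi_pair_connectivity <- function(matrix, roi_a, roi_b) {
  if (is.logical(roi_a)) roi_a <- which(roi_a)
  if (is.logical(roi_b)) roi_b <- which(roi_b)
  if (length(roi_a) == 0 || length(roi_b) == 0) stop("empty ROI mask")
  sub <- matrix[roi_a, roi_b, drop = FALSE]
  if (identical(sort(roi_a), sort(roi_b))) {
    same <- outer(roi_a, roi_b, "==")
    sub[same] <- 0
  }
  mean(sub)
}
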