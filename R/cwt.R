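# Continuous wavelet transform scalograms (analytic Morlet, FFT convolution).
#
# For scale s and angular frequency w the analytic Morlet wavelet has the
# frequency-domain form
#   psi_hat(s w) = pi^(-1/4) sqrt(s) exp(-(s w - w0)^2 / 2),  w > 0,
# with center frequency f_c = (w0 + sqrt(2 + w0^2)) / (4 pi s). The CWT row
# at frequency f is the inverse FFT of X(w) * psi_hat(s_f w). With w0 = 6
# the wavelet offers the usual balance of time and frequency resolution for
# EEG work; a 10 s epoch comfortably holds the 1 Hz wavelet's support.

.cwt_cache <- new.env(parent = emptyenv())

morlet_filter_bank <- function(n, fs, freqs_hz, omega0) {
  key <- paste(n, fs, omega0, length(freqs_hz),
               freqs_hz[1], freqs_hz[length(freqs_hz)], sep = "|")
  hit <- .cwt_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- 0:(n - 1)
  w <- 2 * pi * ifelse(k <= n / 2, k, k - n) * fs / n  # angular freq per bin
  fc <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)       # scale-1 center freq
  filt <- matrix(0, n, length(freqs_hz))
  for (j in seq_along(freqs_hz)) {
    s <- fc / freqs_hz[j]
    filt[, j] <- sqrt(s) * pi^(-0.25) * exp(-0.5 * (s * w - omega0)^2) * (w > 0)
  }
  .cwt_cache[[key]] <- filt
  filt
}

#' Compute the CWT scalogram of one epoch
#'
#' Magnitude of the analytic Morlet continuous wavelet transform on a
#' logarithmically spaced frequency grid spanning 1-100 Hz. Deterministic;
#' the wavelet filter bank is cached per (length, fs, grid) so repeated
#' calls over many epochs are cheap.
#'
#' @param epoch numeric vector of samples, or an `epoch_set` row extracted
#'   by the caller.
#' @param fs sampling rate, Hz.
#' @param n_freqs number of frequency rows (default 96).
#' @param freq_range frequency span, Hz (default `c(1, 100)`).
#' @param omega0 Morlet nondimensional center frequency (default 6).
#' @return an object of class `scalogram`: `magnitudes` (n_freqs x n_times,
#'   all >= 0), `freqs_hz` (ascending), `times_s`, `fs`.
#' @export
cwt_scalogram <- function(epoch, fs, n_freqs = 96, freq_range = c(1, 100),
                          omega0 = 6) {
  x <- as.numeric(epoch)
  if (anyNA(x) || !all(is.finite(x))) {
    stop_arg("epoch contains NA/NaN/Inf samples")
  }
  if (freq_range[1] < 0 || freq_range[2] > fs / 2) {
    stop_arg("`freq_range` must lie within (0, fs/2]")
  }
  n <- length(x)
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_freqs))
  freqs[c(1, n_freqs)] <- freq_range  # pin endpoints against fp drift
  filt <- morlet_filter_bank(n, fs, freqs, omega0)
  X <- stats::fft(x)
  coef <- stats::mvfft(filt * X, inverse = TRUE) / n
  structure(list(magnitudes = t(Mod(coef)), freqs_hz = freqs,
                 times_s = (seq_len(n) - 1) / fs, fs = fs),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d freqs [%g, %g] Hz x %d times (%.1f s)\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              ncol(x$magnitudes), ncol(x$magnitudes) / x$fs))
  invisible(x)
}

#' Total scalogram energy
#' @param scal a `scalogram`.
#' @return sum of squared magnitudes.
#' @export
scalogram_energy <- function(scal) sum(scal$magnitudes^2)
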