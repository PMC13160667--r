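#' Construct a continuous single-channel EEG record
#'
#' The basic container for one stored recording block: a voltage trace in
#' microvolts with its sampling rate and the post-implant latency of its
#' first sample. Chronic monitoring stores data in contiguous 0.5 h
#' intervals; each interval is one `eeg_record`.
#'
#' @param samples numeric vector of voltages (uV); must be non-empty and finite.
#' @param fs sampling rate in Hz (default 500).
#' @param subject_id subject label.
#' @param t0_days post-implant latency of the first sample, in days.
#' @param channel channel label.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs = 500, subject_id = "subj",
                       t0_days = 0, channel = "EEG1") {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_arg("`fs` must be a positive scalar")
  }
  if (length(samples) == 0L) stop_arg("`samples` must be non-empty")
  if (!all(is.finite(samples))) stop_arg("`samples` must be finite")
  structure(
    list(samples = as.numeric(samples), fs = fs,
         subject_id = as.character(subject_id),
         t0_days = as.numeric(t0_days), channel = as.character(channel)),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s/%s: %.1f s @ %g Hz, t0 = %.3f d, RMS %.1f uV\n",
              x$subject_id, x$channel, length(x$samples) / x$fs, x$fs,
              x$t0_days, signal_rms(x$samples)))
  invisible(x)
}

#' Root-mean-square amplitude of a trace
#' @param x numeric vector.
#' @return scalar RMS.
#' @export
signal_rms <- function(x) sqrt(mean(x^2))

#' Generate background EEG as band-limited pink noise
#'
#' Stationary colored-noise stand-in for inter-ictal background activity:
#' Gaussian noise spectrally shaped to a 1/f amplitude profile and
#' band-limited to \[0.5, 100\] Hz, then scaled to a target RMS. Spectral
#' shaping is done in the frequency domain, so the trace is exactly
#' reproducible for a given seed.
#'
#' @param duration_s trace duration in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param seed integer seed (optional).
#' @param rms_uv target RMS amplitude in uV.
#' @param band frequency band retained, Hz.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @export
gen_background <- function(duration_s, fs = 500, seed = NULL, rms_uv = 50,
                           band = c(0.5, 100)) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop_arg("`duration_s` must be a positive scalar")
  }
  n <- as.integer(round(duration_s * fs))
  with_seed(seed, {
    w <- stats::rnorm(n)
    f <- seq(0, fs / 2, length.out = floor(n / 2) + 1L)
    # 1/f amplitude, flat below the band's low edge to avoid a DC blow-up
    amp <- 1 / sqrt(pmax(f, band[1]))
    amp[f < band[1] | f > band[2]] <- 0
    # mirror onto negative frequencies for a real-valued inverse transform
    full <- if (n %% 2L == 0L) c(amp, rev(amp[2:(length(amp) - 1L)]))
            else c(amp, rev(amp[2:length(amp)]))
    x <- Re(stats::fft(stats::fft(w) * full, inverse = TRUE)) / n
    x * (rms_uv / signal_rms(x))
  })
}
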