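# Synthetic ictal and inter-ictal event waveforms.
#
# Convulsive seizures are built from a biphasic spike kernel convolved onto a
# point process whose instantaneous rate stays inside the onset band; SWDs are
# harmonic spike-wave oscillations with a waxing/waning envelope.
#
# Each event is split into a "plan" (all random draws: durations, flags,
# frequencies, a waveform seed) and a deterministic waveform synthesis given
# the plan. Cohort generation stores plans only and renders voltage traces on
# demand, so scheduling is identical whether or not waveforms are realized.

#' Parameters of synthetic convulsive seizures
#'
#' Defaults follow the phenomenology of chronically recorded post-implant
#' convulsive seizures: onset spiking at 1-20 Hz with peak amplitude more
#' than `amp_factor` times the preceding background RMS; an optional
#' mid-ictal depression (MID) of 10-180 s in roughly a quarter of seizures;
#' resumption of lower-frequency spiking at seizure end; post-ictal
#' depression (PID); and an optional inter-ictal multi-spike burst.
#' Onset-only durations average ~38 s.
#'
#' @param onset_freq_range instantaneous spike-rate band during onset, Hz,
#'   within \[1, 20\].
#' @param amp_factor spike peak amplitude as a multiple of background RMS
#'   (must exceed 2).
#' @param p_mid probability that a seizure contains a MID.
#' @param mid_range_s admissible MID durations, seconds.
#' @param mid_mean_excess_s mean of the exponential excess over the MID lower
#'   bound before truncation (gives MID mean ~46 s at the defaults).
#' @param onset_dur_mean_s,onset_dur_shape gamma mean/shape of onset duration.
#' @param end_dur_mean_s,pid_dur_mean_s mean durations of the SZ-end and PID
#'   phases, seconds.
#' @param p_burst probability of a trailing inter-ictal multi-spike burst.
#' @return an object of class `seizure_params`.
#' @export
seizure_params <- function(onset_freq_range = c(2, 18),
                           amp_factor = 3,
                           p_mid = 26 / 99,
                           mid_range_s = c(10, 180),
                           mid_mean_excess_s = 36,
                           onset_dur_mean_s = 38,
                           onset_dur_shape = 6,
                           end_dur_mean_s = 15,
                           pid_dur_mean_s = 20,
                           p_burst = 0.3) {
  if (onset_freq_range[1] < 1 || onset_freq_range[2] > 20 ||
      onset_freq_range[1] >= onset_freq_range[2]) {
    stop_arg("`onset_freq_range` must be an increasing interval within [1, 20]")
  }
  if (amp_factor <= 2) stop_arg("`amp_factor` must exceed 2")
  if (p_mid < 0 || p_mid > 1) stop_arg("`p_mid` must be a probability")
  if (mid_range_s[1] < 10 || mid_range_s[2] > 180 ||
      mid_range_s[1] >= mid_range_s[2]) {
    stop_arg("`mid_range_s` must be an increasing interval within [10, 180]")
  }
  structure(as.list(environment()), class = "seizure_params")
}

#' Parameters of synthetic spike-wave discharges
#'
#' SWDs are stereotyped oscillations with a stable 7-12 Hz fundamental,
#' spike-wave cycle morphology (fundamental plus 2nd/3rd harmonics at fixed
#' phase offsets), sudden onset to full amplitude within one cycle, a
#' waxing/waning amplitude envelope, and an abrupt end. Durations run from
#' 3 s to tens of seconds.
#'
#' @param f0_range fundamental frequency band, Hz, within \[7, 12\].
#' @param dur_range_s admissible durations, seconds (lower bound >= 3).
#' @param dur_mean_excess_s mean exponential excess over the minimum duration
#'   before truncation at the maximum.
#' @param envelope_depth modulation depth of the waxing/waning envelope in
#'   \[0, 1\] (0 = constant amplitude).
#' @param envelope_period_s modulation period, seconds.
#' @param harmonic_weights relative amplitudes of harmonics 1..k.
#' @param harmonic_phases phase offsets (radians) of harmonics 1..k.
#' @param amp_uv peak amplitude in uV at envelope maximum.
#' @return an object of class `swd_params`.
#' @export
swd_params <- function(f0_range = c(7, 12),
                       dur_range_s = c(3, 70),
                       dur_mean_excess_s = 9,
                       envelope_depth = 0.5,
                       envelope_period_s = 2.5,
                       harmonic_weights = c(1, 0.45, 0.22),
                       harmonic_phases = c(0, 1.1, 2.3),
                       amp_uv = 160) {
  if (f0_range[1] < 7 || f0_range[2] > 12 || f0_range[1] > f0_range[2]) {
    stop_arg("`f0_range` must lie within [7, 12] Hz")
  }
  if (dur_range_s[1] < 3 || dur_range_s[1] >= dur_range_s[2]) {
    stop_arg("`dur_range_s` must be increasing with lower bound >= 3 s")
  }
  if (envelope_depth < 0 || envelope_depth > 1) {
    stop_arg("`envelope_depth` must be in [0, 1]")
  }
  structure(as.list(environment()), class = "swd_params")
}

# Biphasic sharp transient (difference of Gaussians), peak-normalized.
spike_kernel <- function(fs, sigma1_ms = 8, sigma2_ms = 18, ratio = 0.55) {
  half <- round(4 * sigma2_ms / 1000 * fs)
  t <- (-half:half) / fs * 1000  # ms
  k <- exp(-t^2 / (2 * sigma1_ms^2)) - ratio * exp(-t^2 / (2 * sigma2_ms^2))
  k / max(abs(k))
}

# Spike train: kernel convolved onto a point process with the given
# instantaneous rate profile; per-spike amplitude jitter with a hard floor so
# the peak-amplitude contract versus background RMS holds.
spike_train <- function(duration_s, fs, rate_hz, amp_floor, amp_scale = 1.25) {
  n <- max(1L, round(duration_s * fs))
  x <- numeric(n)
  kern <- spike_kernel(fs)
  half <- (length(kern) - 1L) %/% 2L
  t <- 0
  while (t < duration_s) {
    r <- if (length(rate_hz) == 2L) stats::runif(1, rate_hz[1], rate_hz[2]) else rate_hz
    t <- t + 1 / r * stats::runif(1, 0.8, 1.2)
    idx <- round(t * fs)
    if (idx >= 1L && idx <= n) {
      amp <- amp_floor * stats::runif(1, 1.02, amp_scale) *
        sample(c(1, -1), 1, prob = c(0.8, 0.2))
      lo <- idx - half
      hi <- idx + half
      klo <- 1L + max(0L, 1L - lo)
      khi <- length(kern) - max(0L, hi - n)
      seg <- max(1L, lo):min(n, hi)
      x[seg] <- x[seg] + amp * kern[klo:khi]
    }
  }
  x
}

rtrunc_exp <- function(n, min_v, mean_excess, max_v) {
  pmin(min_v + stats::rexp(n, rate = 1 / mean_excess), max_v)
}

# Closed-form mean of min(min_v + Exp(mean_excess), max_v); calibrates the
# SWD seconds-per-interval schedule.
mean_trunc_exp <- function(min_v, mean_excess, max_v) {
  min_v + mean_excess * (1 - exp(-(max_v - min_v) / mean_excess))
}

wave_seed_draw <- function() sample.int(2147483646L, 1L)

# ---- seizure plan / synthesis ------------------------------------------------

seizure_plan <- function(params) {
  onset_dur <- max(5, stats::rgamma(1, shape = params$onset_dur_shape,
                                    scale = params$onset_dur_mean_s / params$onset_dur_shape))
  has_mid <- stats::runif(1) < params$p_mid
  phases <- data.frame(phase = "sz_onset", duration_s = onset_dur,
                       stringsAsFactors = FALSE)
  if (has_mid) {
    mid_dur <- rtrunc_exp(1, params$mid_range_s[1], params$mid_mean_excess_s,
                          params$mid_range_s[2])
    end_dur <- max(3, stats::rgamma(1, shape = 4, scale = params$end_dur_mean_s / 4))
    phases <- rbind(phases,
                    data.frame(phase = c("mid", "sz_end"),
                               duration_s = c(mid_dur, end_dur)))
  }
  pid_dur <- max(5, stats::rgamma(1, shape = 4, scale = params$pid_dur_mean_s / 4))
  phases <- rbind(phases, data.frame(phase = "pid", duration_s = pid_dur))
  if (stats::runif(1) < params$p_burst) {
    phases <- rbind(phases, data.frame(phase = "ied_burst", duration_s = 1.5))
  }
  phases$start_s <- c(0, cumsum(phases$duration_s))[seq_len(nrow(phases))]
  list(klass = "seizure", phases = phases[, c("phase", "start_s", "duration_s")],
       total_s = sum(phases$duration_s), wave_seed = wave_seed_draw())
}

seizure_waveform <- function(plan, params, background_rms, fs) {
  with_seed(plan$wave_seed, {
    amp_floor <- params$amp_factor * background_rms
    waves <- lapply(seq_len(nrow(plan$phases)), function(i) {
      ph <- plan$phases$phase[i]
      d <- plan$phases$duration_s[i]
      switch(ph,
        sz_onset  = spike_train(d, fs, params$onset_freq_range, amp_floor),
        mid       = gen_background(d, fs, rms_uv = 0.3 * background_rms),
        sz_end    = spike_train(d, fs, c(1, 4), amp_floor, amp_scale = 1.1),
        pid       = gen_background(d, fs, rms_uv = 0.25 * background_rms),
        ied_burst = spike_train(d, fs, c(4, 6), amp_floor, amp_scale = 1.1))
    })
    unlist(waves, use.names = FALSE)
  })
}

#' Generate one convulsive seizure waveform with phase annotations
#'
#' Concatenates, in order: seizure-onset spiking (instantaneous rate inside
#' the onset band, peak amplitude above `amp_factor` times the supplied
#' background RMS), an optional mid-ictal depression (amplitude suppressed
#' below background), lower-frequency end-of-seizure spiking, post-ictal
#' depression, and an optional inter-ictal multi-spike burst. The returned
#' phase table tiles the waveform exactly.
#'
#' @param params a [seizure_params()] object.
#' @param background_rms RMS of the surrounding background trace, uV.
#' @param fs sampling rate, Hz.
#' @param seed optional integer seed.
#' @return list with `waveform` (numeric vector) and `phases` (data.frame
#'   with columns `phase`, `start_s`, `duration_s`).
#' @export
gen_seizure <- function(params = seizure_params(), background_rms = 50,
                        fs = 500, seed = NULL) {
  stopifnot(inherits(params, "seizure_params"))
  with_seed(seed, {
    plan <- seizure_plan(params)
    # phase boundaries snapped to the sample grid so annotations tile exactly
    plan <- snap_plan(plan, fs)
    list(waveform = seizure_waveform(plan, params, background_rms, fs),
         phases = plan$phases)
  })
}

# Round phase durations to whole samples and recompute starts, so that the
# synthesized waveform length matches the annotated durations exactly.
snap_plan <- function(plan, fs) {
  d <- pmax(1L, round(plan$phases$duration_s * fs)) / fs
  plan$phases$duration_s <- d
  plan$phases$start_s <- c(0, cumsum(d))[seq_along(d)]
  plan$total_s <- sum(d)
  plan
}

# ---- SWD plan / synthesis ----------------------------------------------------

swd_plan <- function(params, duration_s = NULL) {
  f0 <- stats::runif(1, params$f0_range[1], params$f0_range[2])
  dur <- duration_s %||% rtrunc_exp(1, params$dur_range_s[1],
                                    params$dur_mean_excess_s,
                                    params$dur_range_s[2])
  list(klass = "swd", f0 = f0, total_s = dur,
       env_phase = stats::runif(1, 0, 2 * pi))
}

swd_waveform <- function(plan, params, fs) {
  n <- max(1L, round(plan$total_s * fs))
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (k in seq_along(params$harmonic_weights)) {
    x <- x + params$harmonic_weights[k] *
      cos(2 * pi * k * plan$f0 * t + params$harmonic_phases[k])
  }
  x <- x / max(abs(x))
  env <- 1 - params$envelope_depth *
    (0.5 + 0.5 * sin(2 * pi * t / params$envelope_period_s + plan$env_phase))
  params$amp_uv * x * env * pmin(t * plan$f0, 1)  # full amplitude in one cycle
}

#' Generate one spike-wave discharge waveform
#'
#' Harmonic oscillation with a fundamental drawn from `f0_range`, asymmetric
#' spike-wave cycles from fixed-phase harmonics, full amplitude within one
#' cycle of onset, a waxing/waning envelope, and an abrupt offset.
#'
#' @param params a [swd_params()] object.
#' @param fs sampling rate, Hz.
#' @param seed optional integer seed.
#' @param duration_s fixed duration; if `NULL`, drawn from the duration model.
#' @return list with `waveform`, `f0` (Hz) and `duration_s`.
#' @export
gen_swd <- function(params = swd_params(), fs = 500, seed = NULL,
                    duration_s = NULL) {
  stopifnot(inherits(params, "swd_params"))
  with_seed(seed, {
    plan <- swd_plan(params, duration_s)
    plan$total_s <- max(1L, round(plan$total_s * fs)) / fs
    list(waveform = swd_waveform(plan, params, fs),
         f0 = plan$f0, duration_s = plan$total_s)
  })
}
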