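# Synthetic EEG generator: background, event morphology, scheduling.

test_that("background traces have the right length, determinism and stationarity", {
  x <- gen_background(1800, 500, seed = 1)
  expect_length(x, 900000L)
  expect_identical(x, gen_background(1800, 500, seed = 1))
  expect_false(identical(x, gen_background(1800, 500, seed = 2)))
  # stationary RMS: two disjoint 60 s windows agree within 20%
  r1 <- signal_rms(x[1:30000])
  r2 <- signal_rms(x[600001:630000])
  expect_lt(abs(r1 - r2) / r1, 0.2)
  expect_error(gen_background(-5, 500), "positive")
})

test_that("background power is band-limited and decays with frequency", {
  x <- gen_background(120, 500, seed = 3)
  spec <- Mod(stats::fft(x))^2
  f <- (seq_along(spec) - 1) * 500 / length(spec)
  half <- f <= 250
  band_power <- function(lo, hi) sum(spec[half & f >= lo & f <= hi])
  expect_gt(band_power(1, 10), band_power(40, 100))        # 1/f decay
  expect_lt(band_power(110, 240), 1e-6 * band_power(0.5, 100))  # band limit
})

test_that("seizures tile their phase annotations exactly and in order", {
  sz <- gen_seizure(seizure_params(p_mid = 1, p_burst = 0), seed = 4)
  expect_identical(sz$phases$phase, c("sz_onset", "mid", "sz_end", "pid"))
  # contiguous, non-overlapping tiling of the waveform
  expect_equal(sz$phases$start_s,
               c(0, cumsum(sz$phases$duration_s))[seq_len(nrow(sz$phases))])
  expect_equal(length(sz$waveform) / 500, sum(sz$phases$duration_s))

  no_mid <- gen_seizure(seizure_params(p_mid = 0, p_burst = 0), seed = 5)
  expect_false("mid" %in% no_mid$phases$phase)
  # without MID the seizure proper is the onset spiking alone
  ict <- no_mid$phases[no_mid$phases$phase != "pid", , drop = FALSE]
  expect_identical(ict$phase, "sz_onset")
})

test_that("seizure peak amplitude exceeds amp_factor x background RMS", {
  for (seed in 1:5) {
    sz <- gen_seizure(seizure_params(), background_rms = 50, seed = seed)
    on <- sz$phases[sz$phases$phase == "sz_onset", ]
    onset <- sz$waveform[seq_len(round(on$duration_s * 500))]
    expect_gt(max(abs(onset)), 3 * 50)
    # MID (when present) is suppressed below background
    if ("mid" %in% sz$phases$phase) {
      m <- sz$phases[sz$phases$phase == "mid", ]
      mid <- sz$waveform[round(m$start_s * 500) + seq_len(round(m$duration_s * 500))]
      expect_lt(signal_rms(mid), 50)
    }
  }
})

test_that("MID durations always fall in [10, 180] s", {
  set.seed(42)
  pars <- seizure_params(p_mid = 1)
  durs <- replicate(1000, {
    pl <- scalodetect:::seizure_plan(pars)
    pl$phases$duration_s[pl$phases$phase == "mid"]
  })
  expect_true(all(durs >= 10 - 1e-9 & durs <= 180 + 1e-9))
})

test_that("SWD waveforms keep a 7-12 Hz fundamental with spike-wave shape", {
  sw <- gen_swd(swd_params(f0_range = c(9, 9)), fs = 500, seed = 6,
                duration_s = 10)
  spec <- Mod(stats::fft(sw$waveform))
  f <- (seq_along(spec) - 1) * 500 / length(spec)
  peak <- f[which.max(spec[f > 0.5 & f <= 250]) + sum(f <= 0.5)]
  expect_lt(abs(peak - 9), 0.2)  # FFT resolution 0.1 Hz on a 10 s epoch

  set.seed(7)
  f0s <- replicate(1000, gen_swd(fs = 100, duration_s = 1)$f0)
  expect_true(all(f0s >= 7 & f0s <= 12))
  durs <- replicate(200, gen_swd(fs = 100)$duration_s)
  expect_true(all(durs >= 3))
})

test_that("zero envelope depth gives a constant-amplitude oscillation", {
  sw <- gen_swd(swd_params(envelope_depth = 0, f0_range = c(8, 8)),
                fs = 500, seed = 8, duration_s = 10)
  x <- sw$waveform
  # per-cycle peaks after the one-cycle onset ramp
  cyc <- split(abs(x[round(500 / 8):length(x)]),
               ceiling(seq_along(x[round(500 / 8):length(x)]) / (500 / 8)))
  peaks <- vapply(cyc, max, numeric(1))
  expect_lt(stats::sd(peaks) / mean(peaks), 0.02)

  waxing <- gen_swd(swd_params(envelope_depth = 0.8, f0_range = c(8, 8)),
                    fs = 500, seed = 8, duration_s = 10)
  cycw <- split(abs(waxing$waveform[63:5000]),
                ceiling(seq_along(waxing$waveform[63:5000]) / 62.5))
  peaksw <- vapply(cycw, max, numeric(1))
  expect_gt(stats::sd(peaksw) / mean(peaksw), 0.1)
})

test_that("subject schedules respect latency classes and SWD presence", {
  prof <- subject_profile("FPI_Stress", n_early = 3, n_late = 2)
  s <- gen_subject(prof, "rat1", n_days = 7, intervals_per_day = 2,
                   fs = 250, seed = 9)
  sz <- s$annotations[s$annotations$klass == "seizure", ]
  expect_true(all(sz$latency_days[sz$latency_class == "early"] <= 5))
  expect_true(all(sz$latency_days[sz$latency_class == "late"] > 5))
  expect_equal(length(unique(sz$event_id)), 5L)

  # no-seizure subjects still carry SWDs
  quiet <- gen_subject(subject_profile("Sham_noStress"), "rat2",
                       n_days = 2, intervals_per_day = 2, fs = 250, seed = 10)
  expect_false("seizure" %in% quiet$annotations$klass)
  expect_gt(sum(quiet$annotations$klass == "swd"), 0)
})

test_that("events lie within their intervals and never overlap", {
  prof <- subject_profile("FPI_Stress", n_early = 4, n_late = 3)
  s <- gen_subject(prof, "rat3", n_days = 7, intervals_per_day = 2,
                   fs = 250, seed = 11)
  ann <- s$annotations
  expect_true(all(ann$start_s >= 0))
  expect_true(all(ann$start_s + ann$duration_s <= 1800 + 1e-9))
  for (ii in unique(ann$interval_index)) {
    a <- ann[ann$interval_index == ii, ]
    ev <- do.call(rbind, lapply(split(a, a$event_id), function(d) {
      data.frame(lo = min(d$start_s), hi = max(d$start_s + d$duration_s))
    }))
    ev <- ev[order(ev$lo), ]
    if (nrow(ev) > 1) {
      expect_true(all(ev$lo[-1] >= ev$hi[-nrow(ev)] - 1e-9))
    }
  }
})

test_that("SWD load grows to the plateau by day 90", {
  prof <- subject_profile("Sham_Stress")
  s <- gen_subject(prof, "rat4", n_days = 94, intervals_per_day = 3,
                   fs = 250, seed = 12)
  swd <- s$annotations[s$annotations$klass == "swd", ]
  per_int <- vapply(split(swd$duration_s, swd$interval_index), sum, numeric(1))
  lat <- s$intervals$latency_days[match(as.integer(names(per_int)),
                                        s$intervals$interval_index)]
  plateau_mean <- mean(per_int[lat >= 88])
  early_mean <- mean(per_int[lat <= 2])
  # plateau target 100 s/interval, day-0 target 10 s/interval
  expect_lt(abs(plateau_mean - 100), 30)
  expect_lt(early_mean, 40)
  expect_gt(plateau_mean, 2 * early_mean)
})

test_that("cohorts are pure functions of (config, seed)", {
  cfg <- cohort_config(n_per_group = 2, n_days = 2, intervals_per_day = 2,
                       fs = 250, pte_fraction = 0)
  co1 <- gen_cohort(cfg, seed = 5)
  co2 <- gen_cohort(cfg, seed = 5)
  expect_equal(nrow(co1$manifest$subjects), 8L)
  expect_identical(co1$annotations, co2$annotations)
  # byte-identical annotation exports
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_annotations_csv(co1$annotations, f1)
  write_annotations_csv(co2$annotations, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # rendered records are reproducible too
  expect_identical(cohort_record(co1, "Sham_Stress_01", 1)$samples,
                   cohort_record(co2, "Sham_Stress_01", 1)$samples)
})

test_that("late seizures stay inside FPI_Stress under the default design", {
  cfg <- cohort_config(n_per_group = 2, n_days = 7, intervals_per_day = 1,
                       fs = 250, pte_fraction = 0.25)
  co <- gen_cohort(cfg, seed = 13)
  m <- co$manifest$subjects
  expect_true(all(m$group[m$has_late] == "FPI_Stress"))
  expect_equal(sum(m$has_late), 2L)  # round(0.25 * 8)
  expect_error(subject_profile("Sham_Stress", n_late = 1), "FPI_Stress")
  expect_silent(subject_profile("Sham_Stress", n_late = 1,
                                allow_late_override = TRUE))
})

test_that("degenerate cohort configurations are rejected", {
  expect_error(cohort_config(groups = character(0)), "non-empty")
  expect_error(cohort_config(n_per_group = 0), ">= 1")
  expect_error(cohort_config(pte_fraction = 0.9, n_per_group = 2), "PTE")
})
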