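# Subject-level scheduling: early/late seizures and an SWD load that grows
# with post-implant latency, placed into 0.5 h recording intervals.

#' Subject-level simulation profile
#'
#' Describes one animal in a four-group chronic-monitoring design
#' (injury x pre-injury stress). "Early" seizures occur at post-implant
#' latencies of at most 5 days; "late" seizures (after 5 days) define
#' post-traumatic epilepsy (PTE). By default only `FPI_Stress` subjects may
#' carry late seizures, mirroring the observed cohort; set
#' `allow_late_override = TRUE` to lift the restriction.
#'
#' @param group one of `"FPI_Stress"`, `"FPI_noStress"`, `"Sham_Stress"`,
#'   `"Sham_noStress"`.
#' @param n_early,n_late numbers of early / late convulsive seizures.
#' @param swd_rate_params named vector `c(initial, plateau, plateau_day)`:
#'   SWD seconds per 0.5 h interval at day 0, at plateau, and the day the
#'   plateau is reached (defaults 10 s -> 100 s by day 90).
#' @param allow_late_override allow late seizures outside `FPI_Stress`.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(group,
                            n_early = 0L, n_late = 0L,
                            swd_rate_params = c(initial = 10, plateau = 100,
                                                plateau_day = 90),
                            allow_late_override = FALSE) {
  groups <- c("FPI_Stress", "FPI_noStress", "Sham_Stress", "Sham_noStress")
  group <- match.arg(group, groups)
  if (n_early < 0 || n_late < 0) stop_arg("seizure counts must be >= 0")
  if (n_late > 0 && group != "FPI_Stress" && !allow_late_override) {
    stop_arg("late seizures are restricted to FPI_Stress subjects ",
             "(use allow_late_override = TRUE to lift)")
  }
  stopifnot(all(c("initial", "plateau", "plateau_day") %in% names(swd_rate_params)))
  structure(list(group = group,
                 has_early = n_early > 0L, has_late = n_late > 0L,
                 n_early = as.integer(n_early), n_late = as.integer(n_late),
                 swd_rate_params = swd_rate_params),
            class = "subject_profile")
}

# Target SWD seconds per interval at a given post-implant latency: linear
# growth from `initial` at day 0 to `plateau` at `plateau_day`, flat after.
swd_target_s <- function(swd_rate_params, latency_days) {
  p <- swd_rate_params
  p[["initial"]] + (p[["plateau"]] - p[["initial"]]) *
    pmin(latency_days / p[["plateau_day"]], 1)
}

#' Generate one subject's recording schedule and ground-truth annotations
#'
#' Samples `intervals_per_day` half-hour recording intervals per simulated
#' day, schedules early seizures at latencies of at most 5 d and late
#' seizures after 5 d, and fills every interval with SWDs whose expected
#' total seconds follow the subject's latency-dependent rate schedule.
#' Events never span interval boundaries. The return value holds plans and
#' seeds, not voltages; use [render_interval()] to synthesize any interval's
#' trace reproducibly.
#'
#' @param profile a [subject_profile()].
#' @param subject_id subject label (also keys the RNG stream).
#' @param n_days number of simulated post-implant days (> 0).
#' @param intervals_per_day sampled 0.5 h intervals per day.
#' @param fs sampling rate, Hz.
#' @param interval_s stored-interval length, seconds (default 1800).
#' @param seed integer seed.
#' @param background_rms background RMS amplitude, uV.
#' @param seizure_early,seizure_late [seizure_params()] for the two latency
#'   classes (defaults make early seizures shorter than late ones, total
#'   durations ~52 s vs ~83 s).
#' @param swd [swd_params()] for spike-wave discharges.
#' @return an object of class `eeg_subject` with elements `intervals`
#'   (data.frame `interval_index`, `latency_days`), `annotations`
#'   (data.frame), and `schedule` (per-interval event plans).
#' @export
gen_subject <- function(profile, subject_id = "subj",
                        n_days = 6, intervals_per_day = 4,
                        fs = 500, interval_s = 1800, seed = NULL,
                        background_rms = 50,
                        seizure_early = seizure_params(onset_dur_mean_s = 36),
                        seizure_late = seizure_params(onset_dur_mean_s = 67),
                        swd = swd_params()) {
  stopifnot(inherits(profile, "subject_profile"))
  if (n_days <= 0) stop_arg("`n_days` must be > 0")
  interval_days <- interval_s / 86400
  with_seed(seed, {
    n_int <- as.integer(n_days * intervals_per_day)
    day <- rep(seq_len(n_days) - 1L, each = intervals_per_day)
    latency <- sort(day + stats::runif(n_int, 0, 1 - interval_days))
    intervals <- data.frame(interval_index = seq_len(n_int) - 1L,
                            latency_days = latency)

    early_ok <- which(latency <= 5 - interval_days)
    late_ok <- which(latency > 5)
    if (profile$n_early > 0 && length(early_ok) == 0) {
      stop_arg("no intervals at latency <= 5 d available for early seizures")
    }
    if (profile$n_late > 0 && length(late_ok) == 0) {
      stop_arg("no intervals at latency > 5 d available for late seizures; ",
               "increase `n_days`")
    }
    assign_cap <- function(pool, n, cap = 3L) {
      # sample interval slots with replacement, capping events per interval
      out <- integer(0)
      for (i in seq_len(n)) {
        open <- pool[tabulate(match(out, pool), length(pool)) < cap]
        if (length(open) == 0L) open <- pool
        out <- c(out, if (length(open) == 1L) open else sample(open, 1L))
      }
      out
    }
    sz_int <- c(assign_cap(early_ok, profile$n_early),
                assign_cap(late_ok, profile$n_late))
    sz_class <- rep(c("early", "late"), c(profile$n_early, profile$n_late))

    schedule <- vector("list", n_int)
    ann <- list()
    for (k in seq_len(n_int)) {
      events <- list()
      idx <- which(sz_int == k)
      for (j in idx) {
        pars <- if (sz_class[j] == "early") seizure_early else seizure_late
        pl <- snap_plan(seizure_plan(pars), fs)
        pl$latency_class <- sz_class[j]
        events[[length(events) + 1L]] <- pl
      }
      target <- swd_target_s(profile$swd_rate_params, latency[k])
      e_dur <- mean_trunc_exp(swd$dur_range_s[1], swd$dur_mean_excess_s,
                              swd$dur_range_s[2])
      n_swd <- stats::rpois(1, target / e_dur)
      for (j in seq_len(n_swd)) {
        pl <- swd_plan(swd)
        pl$total_s <- max(1L, round(pl$total_s * fs)) / fs
        events[[length(events) + 1L]] <- pl
      }
      # capacity guard: drop SWDs (never seizures) if the interval overflows
      total <- function(ev) sum(vapply(ev, `[[`, numeric(1), "total_s"))
      while (length(events) > 0 && total(events) > 0.85 * interval_s) {
        swd_idx <- which(vapply(events, `[[`, character(1), "klass") == "swd")
        if (length(swd_idx) == 0) break
        events[[swd_idx[length(swd_idx)]]] <- NULL
      }
      if (length(events) > 0 && total(events) > interval_s) {
        stop_arg("scheduled seizures exceed the ", interval_s,
                 " s interval; use longer intervals or fewer seizures")
      }
      if (length(events) > 0) {
        events <- events[sample.int(length(events))]
        durs <- vapply(events, `[[`, numeric(1), "total_s")
        free <- interval_s - sum(durs)
        u <- stats::rexp(length(events) + 1L)
        gaps <- free * u / sum(u)
        starts <- floor((cumsum(gaps)[seq_along(events)] +
                           c(0, cumsum(durs))[seq_along(events)]) * fs) / fs
        # grid snapping may shave a gap below one sample; keep events disjoint
        for (j in seq_along(events)) {
          if (j > 1L) starts[j] <- max(starts[j], starts[j - 1L] + durs[j - 1L])
          events[[j]]$start_s <- starts[j]
        }
      }
      schedule[[k]] <- list(interval_index = k - 1L,
                            latency_days = latency[k],
                            bg_seed = derive_seed(wave_seed_draw(), "bg"),
                            events = events)
      for (j in seq_along(events)) {
        ev <- events[[j]]
        eid <- sprintf("%s_i%03d_e%02d", subject_id, k - 1L, j)
        if (ev$klass == "seizure") {
          ann[[length(ann) + 1L]] <- data.frame(
            subject_id = subject_id, interval_index = k - 1L,
            latency_days = latency[k], event_id = eid, klass = "seizure",
            phase = ev$phases$phase,
            start_s = ev$start_s + ev$phases$start_s,
            duration_s = ev$phases$duration_s,
            latency_class = ev$latency_class, stringsAsFactors = FALSE)
        } else {
          ann[[length(ann) + 1L]] <- data.frame(
            subject_id = subject_id, interval_index = k - 1L,
            latency_days = latency[k], event_id = eid, klass = "swd",
            phase = "whole", start_s = ev$start_s, duration_s = ev$total_s,
            latency_class = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(subject_id = character(0), interval_index = integer(0),
                 latency_days = numeric(0), event_id = character(0),
                 klass = character(0), phase = character(0),
                 start_s = numeric(0), duration_s = numeric(0),
                 latency_class = character(0), stringsAsFactors = FALSE)
    structure(list(subject_id = subject_id, profile = profile,
                   fs = fs, interval_s = interval_s,
                   background_rms = background_rms,
                   seizure_early = seizure_early, seizure_late = seizure_late,
                   swd = swd,
                   intervals = intervals, annotations = annotations,
                   schedule = schedule),
              class = "eeg_subject")
  })
}

#' @export
print.eeg_subject <- function(x, ...) {
  nsz <- length(unique(x$annotations$event_id[x$annotations$klass == "seizure"]))
  nswd <- sum(x$annotations$klass == "swd")
  cat(sprintf("<eeg_subject> %s (%s): %d intervals @ %g Hz, %d seizures, %d SWDs\n",
              x$subject_id, x$profile$group, nrow(x$intervals), x$fs, nsz, nswd))
  invisible(x)
}

#' Synthesize the voltage trace of one recording interval
#'
#' Renders a scheduled 0.5 h interval as an [eeg_record()]: seeded pink-noise
#' background with every planned event waveform inserted at its annotated
#' position. Rendering is deterministic, so records can be regenerated on
#' demand instead of held in memory.
#'
#' @param subject an `eeg_subject` from [gen_subject()].
#' @param interval_index 0-based interval index.
#' @return an [eeg_record()] whose `t0_days` is the interval latency.
#' @export
render_interval <- function(subject, interval_index) {
  stopifnot(inherits(subject, "eeg_subject"))
  k <- interval_index + 1L
  if (k < 1L || k > length(subject$schedule)) {
    stop_arg("interval_index out of range")
  }
  sch <- subject$schedule[[k]]
  fs <- subject$fs
  bg <- gen_background(subject$interval_s, fs, seed = sch$bg_seed,
                       rms_uv = subject$background_rms)
  for (ev in sch$events) {
    wave <- if (ev$klass == "seizure") {
      pars <- if (ev$latency_class == "early") subject$seizure_early
              else subject$seizure_late
      seizure_waveform(ev, pars, subject$background_rms, fs)
    } else {
      swd_waveform(ev, subject$swd, fs)
    }
    i0 <- round(ev$start_s * fs) + 1L
    idx <- i0:(i0 + length(wave) - 1L)
    keep <- if (ev$klass == "seizure") 0.3 else 0.4
    bg[idx] <- keep * bg[idx] + wave
  }
  eeg_record(bg, fs = fs, subject_id = subject$subject_id,
             t0_days = sch$latency_days, channel = "EEG1")
}
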