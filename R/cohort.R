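# Cohort assembly: a four-group chronic-monitoring design with reproducible
# per-subject RNG streams derived from one master seed.

#' Configuration of a synthetic EEG cohort
#'
#' Describes a scaled stand-in for a chronic video-EEG cohort with four
#' treatment groups (fluid-percussion injury x pre-injury stress). The
#' default cohort is small (2 subjects per group over 6 sampled days) so the
#' full detection pipeline runs in minutes; full-scale configurations are
#' legal but not the default. A fixed fraction `pte_fraction` of the cohort
#' develops PTE (late seizures); those subjects are drawn deterministically
#' from `pte_groups` so the planted incidence is exact.
#'
#' @param n_per_group subjects per group (scalar, or named vector over groups).
#' @param groups group labels.
#' @param n_days simulated post-implant days.
#' @param intervals_per_day sampled 0.5 h intervals per day.
#' @param fs sampling rate, Hz.
#' @param interval_s interval length, seconds.
#' @param background_rms background RMS amplitude, uV.
#' @param pte_fraction fraction of all subjects carrying late seizures.
#' @param pte_groups groups allowed to carry late seizures.
#' @param p_early probability a subject has early seizures.
#' @param n_early_mean,n_late_mean mean seizure counts (>= 1) for subjects
#'   that have them.
#' @param swd_rate_params per-subject SWD load schedule, see
#'   [subject_profile()].
#' @param seizure_early,seizure_late,swd event parameter objects.
#' @param swd_group_overrides optional named list (group -> [swd_params()])
#'   replacing the shared SWD generator for specific groups — e.g. a
#'   group-specific frequency shift as a positive control for the group
#'   comparison; the default `NULL` keeps SWDs identical in all groups.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 2,
                          groups = c("FPI_Stress", "FPI_noStress",
                                     "Sham_Stress", "Sham_noStress"),
                          n_days = 6, intervals_per_day = 4,
                          fs = 500, interval_s = 1800, background_rms = 50,
                          pte_fraction = 5 / 61, pte_groups = "FPI_Stress",
                          p_early = 0.5, n_early_mean = 2, n_late_mean = 2,
                          swd_rate_params = c(initial = 10, plateau = 100,
                                              plateau_day = 90),
                          seizure_early = seizure_params(onset_dur_mean_s = 36),
                          seizure_late = seizure_params(onset_dur_mean_s = 67),
                          swd = swd_params(), swd_group_overrides = NULL) {
  if (length(groups) == 0) stop_arg("`groups` must be non-empty")
  if (!is.null(swd_group_overrides)) {
    ok <- all(names(swd_group_overrides) %in% groups) &&
      all(vapply(swd_group_overrides, inherits, logical(1), "swd_params"))
    if (!ok) stop_arg("`swd_group_overrides` must map group names to swd_params")
  }
  if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), length(groups)),
                                   groups)
  }
  if (!all(groups %in% names(n_per_group)) || any(n_per_group < 1)) {
    stop_arg("`n_per_group` must name every group with a count >= 1")
  }
  if (pte_fraction < 0 || pte_fraction > 1) {
    stop_arg("`pte_fraction` must be in [0, 1]")
  }
  n_total <- sum(n_per_group[groups])
  n_pte <- round(pte_fraction * n_total)
  if (n_pte > sum(n_per_group[intersect(groups, pte_groups)])) {
    stop_arg("`pte_fraction` asks for more PTE subjects than `pte_groups` hold")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a reproducible synthetic EEG cohort
#'
#' Builds per-subject profiles and schedules under one master seed.
#' Per-subject RNG streams are derived by stable hashing of the subject id,
#' so the cohort is a pure function of `(config, seed)` and subjects can be
#' regenerated independently. Voltage traces are rendered lazily via
#' [render_interval()] / [cohort_record()].
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @return an object of class `eeg_cohort` with elements `subjects` (list of
#'   `eeg_subject`), `annotations` (combined data.frame with a `group`
#'   column), and `manifest`.
#' @export
gen_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- sum(config$n_per_group[config$groups])
  n_pte <- round(config$pte_fraction * n_total)

  ids <- unlist(lapply(config$groups, function(g) {
    sprintf("%s_%02d", g, seq_len(config$n_per_group[[g]]))
  }))
  grp <- rep(config$groups, config$n_per_group[config$groups])

  # deterministic PTE assignment: first subjects of the eligible groups
  eligible <- which(grp %in% config$pte_groups)
  pte_idx <- eligible[seq_len(n_pte)]

  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sseed <- derive_seed(seed, ids[i])
    prof <- with_seed(derive_seed(sseed, "profile"), {
      has_early <- stats::runif(1) < config$p_early
      n_early <- if (has_early) 1L + stats::rpois(1, config$n_early_mean - 1) else 0L
      n_late <- if (i %in% pte_idx) 1L + stats::rpois(1, config$n_late_mean - 1) else 0L
      subject_profile(grp[i], n_early = n_early, n_late = n_late,
                      swd_rate_params = config$swd_rate_params,
                      allow_late_override = !identical(config$pte_groups,
                                                       "FPI_Stress"))
    })
    subjects[[i]] <- gen_subject(
      prof, subject_id = ids[i],
      n_days = config$n_days, intervals_per_day = config$intervals_per_day,
      fs = config$fs, interval_s = config$interval_s,
      seed = derive_seed(sseed, "schedule"),
      background_rms = config$background_rms,
      seizure_early = config$seizure_early,
      seizure_late = config$seizure_late,
      swd = config$swd_group_overrides[[grp[i]]] %||% config$swd)
  }
  names(subjects) <- ids

  ann <- do.call(rbind, lapply(subjects, `[[`, "annotations"))
  rownames(ann) <- NULL
  ann$group <- grp[match(ann$subject_id, ids)]

  manifest <- list(
    seed = seed,
    groups = as.list(stats::setNames(as.integer(config$n_per_group[config$groups]),
                                     config$groups)),
    subjects = data.frame(
      subject_id = ids, group = grp,
      has_early = vapply(subjects, function(s) s$profile$has_early, logical(1)),
      has_late = vapply(subjects, function(s) s$profile$has_late, logical(1)),
      n_early = vapply(subjects, function(s) s$profile$n_early, integer(1)),
      n_late = vapply(subjects, function(s) s$profile$n_late, integer(1)),
      n_intervals = vapply(subjects, function(s) nrow(s$intervals), integer(1)),
      stringsAsFactors = FALSE, row.names = NULL))

  structure(list(config = config, seed = seed, subjects = subjects,
                 annotations = ann, manifest = manifest),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  m <- x$manifest$subjects
  cat(sprintf("<eeg_cohort> %d subjects in %d groups, seed %d\n",
              nrow(m), length(unique(m$group)), x$seed))
  cat(sprintf("  PTE subjects: %d; seizure events: %d; SWD events: %d\n",
              sum(m$has_late),
              length(unique(x$annotations$event_id[x$annotations$klass == "seizure"])),
              sum(x$annotations$klass == "swd")))
  invisible(x)
}

#' Render one interval of one cohort subject
#' @param cohort an `eeg_cohort`.
#' @param subject_id subject label.
#' @param interval_index 0-based interval index.
#' @return an [eeg_record()].
#' @export
cohort_record <- function(cohort, subject_id, interval_index) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  subj <- cohort$subjects[[subject_id]]
  if (is.null(subj)) stop_arg("unknown subject_id: ", subject_id)
  render_interval(subj, interval_index)
}
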