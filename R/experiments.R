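# Cross-over training designs and group comparisons on synthetic cohorts.

train_subset_args <- function(subset) {
  switch(subset,
    early_only = list(kind = "seizure", latency_class = "early"),
    late_only = list(kind = "seizure", latency_class = "late"),
    all = list(kind = "seizure", latency_class = NULL),
    all_swd = list(kind = "swd", latency_class = NULL),
    pte_swd_only = list(kind = "swd", latency_class = NULL, pte_only = TRUE),
    stop_arg("unknown training subset: ", subset))
}

# Cache of per-interval epoch images over the intervals of interest, so the
# same scalograms are classified under every training condition.
cache_interval_images <- function(cohort, intervals, img_cfg) {
  out <- vector("list", nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    sid <- intervals$subject_id[r]; ii <- intervals$interval_index[r]
    rec <- cohort_record(cohort, sid, ii)
    eps <- segment_record(rec, interval_index = ii)
    out[[r]] <- list(subject_id = sid, interval_index = ii,
                     latency_days = rec$t0_days,
                     epoch_index = eps$epoch_index,
                     images = epochs_to_images(
                       eps, n_freqs = img_cfg$n_freqs,
                       freq_range = img_cfg$freq_range, omega0 = img_cfg$omega0,
                       height = img_cfg$height, width = img_cfg$width,
                       colormap = img_cfg$colormap, scaling = img_cfg$scaling))
  }
  out
}

predict_cached <- function(model, cache) {
  do.call(rbind, lapply(cache, function(ci) {
    pr <- predict(model, ci$images)
    data.frame(subject_id = ci$subject_id, interval_index = ci$interval_index,
               latency_days = ci$latency_days, epoch_index = ci$epoch_index,
               label = pr$label, confidence = pr$confidence,
               stringsAsFactors = FALSE)
  }))
}

#' Cross-over training experiment
#'
#' Trains a seizure detector separately on early-only, late-only, and all
#' seizures, applies each model to the same scalograms of every
#' seizure-bearing interval in the cohort, and tabulates per-interval total
#' detection durations split by the interval's early/late test class. A
#' two-way ANOVA (training condition x test latency class) on the durations
#' probes whether the training subset matters.
#'
#' @param cohort an `eeg_cohort` containing early and late seizures.
#' @param img_cfg [image_config()] for scalogram images.
#' @param conditions training subsets to run.
#' @param seed integer seed.
#' @param detector_args extra arguments passed to [train_detector()].
#' @return list with `durations` (data.frame `training`, `test_class`,
#'   `subject_id`, `interval_index`, `total_detected_s`), `anova`
#'   (a `stat_result`), and `cell_means`.
#' @export
crossover_experiment <- function(cohort, img_cfg = image_config(),
                                 conditions = c("early_only", "late_only", "all"),
                                 seed = 1, detector_args = list()) {
  ann <- cohort$annotations
  sz <- ann[ann$klass == "seizure", , drop = FALSE]
  if (nrow(sz) == 0) stop_arg("cohort contains no seizures")
  intervals <- unique(sz[, c("subject_id", "interval_index")])
  cache <- cache_interval_images(cohort, intervals, img_cfg)

  durs <- list()
  for (cond in conditions) {
    sel <- train_subset_args(cond)
    ts <- tryCatch(
      make_training_set(cohort, kind = sel$kind,
                        latency_class = sel$latency_class,
                        img_cfg = img_cfg, seed = derive_seed(seed, cond)),
      error = function(e) NULL)
    if (is.null(ts)) {
      message("crossover: no events for condition '", cond, "'; skipped")
      next
    }
    model <- do.call(train_detector,
                     c(list(ts, img_cfg = img_cfg,
                            seed = derive_seed(seed, paste0("fit_", cond))),
                       detector_args))
    preds <- predict_cached(model, cache)
    for (r in seq_len(nrow(intervals))) {
      sid <- intervals$subject_id[r]; ii <- intervals$interval_index[r]
      pr <- preds[preds$subject_id == sid & preds$interval_index == ii, ,
                  drop = FALSE]
      agg <- aggregate_interval(pr)
      durs[[length(durs) + 1L]] <- data.frame(
        training = cond,
        test_class = classify_latency(pr$latency_days[1]),
        subject_id = sid, interval_index = ii,
        total_detected_s = agg$total_detected_s, stringsAsFactors = FALSE)
    }
  }
  durations <- do.call(rbind, durs)
  anova <- if (length(unique(durations$training)) >= 2 &&
               length(unique(durations$test_class)) >= 2) {
    anova_two_way(durations$total_detected_s, durations$training,
                  durations$test_class)
  } else NULL
  cell_means <- stats::aggregate(total_detected_s ~ training + test_class,
                                 durations, mean)
  list(durations = durations, anova = anova, cell_means = cell_means)
}

#' Per-group SWD detection durations under two training regimes
#'
#' Trains an SWD detector on SWDs from all subjects and, separately, on
#' SWDs from PTE subjects only, applies both to the same sampled intervals
#' of every subject, and summarizes per-subject mean detected SWD seconds
#' per 0.5 h interval as group mean +/- SEM. Group tests: pooled-variance t
#' (injury and stress contrasts) and a two-way injury x stress ANOVA on the
#' per-subject means.
#'
#' @param cohort an `eeg_cohort` with SWDs in all groups.
#' @param img_cfg [image_config()].
#' @param regimes training regimes to run.
#' @param intervals_per_subject how many intervals per subject to classify.
#' @param seed integer seed.
#' @param detector_args extra arguments to [train_detector()].
#' @return list with `subject_means`, `group_summary`, `stats` per regime.
#' @export
swd_group_experiment <- function(cohort, img_cfg = image_config(),
                                 regimes = c("all_swd", "pte_swd_only"),
                                 intervals_per_subject = 3, seed = 1,
                                 detector_args = list()) {
  man <- cohort$manifest$subjects
  if (!any(man$has_late) && "pte_swd_only" %in% regimes) {
    message("no PTE subjects: skipping 'pte_swd_only' regime")
    regimes <- setdiff(regimes, "pte_swd_only")
  }
  # sampled evaluation intervals, shared across regimes
  intervals <- with_seed(derive_seed(seed, "eval"), {
    do.call(rbind, lapply(man$subject_id, function(sid) {
      iv <- cohort$subjects[[sid]]$intervals$interval_index
      data.frame(subject_id = sid,
                 interval_index = sort(sample(iv, min(length(iv),
                                                      intervals_per_subject))),
                 stringsAsFactors = FALSE)
    }))
  })
  cache <- cache_interval_images(cohort, intervals, img_cfg)

  res <- list()
  for (regime in regimes) {
    sel <- train_subset_args(regime)
    ts <- make_training_set(cohort, kind = "swd",
                            pte_only = isTRUE(sel$pte_only),
                            img_cfg = img_cfg,
                            seed = derive_seed(seed, regime))
    model <- do.call(train_detector,
                     c(list(ts, img_cfg = img_cfg,
                            seed = derive_seed(seed, paste0("fit_", regime))),
                       detector_args))
    preds <- predict_cached(model, cache)
    sm <- do.call(rbind, lapply(unique(intervals$subject_id), function(sid) {
      pr <- preds[preds$subject_id == sid, , drop = FALSE]
      tot <- vapply(split(pr, pr$interval_index),
                    function(d) aggregate_interval(d)$total_detected_s,
                    numeric(1))
      data.frame(subject_id = sid,
                 group = man$group[match(sid, man$subject_id)],
                 mean_s = mean(tot), stringsAsFactors = FALSE)
    }))
    gs <- do.call(rbind, lapply(split(sm, sm$group), function(d) {
      data.frame(group = d$group[1], mean_s = mean(d$mean_s),
                 sem_s = if (nrow(d) > 1) stats::sd(d$mean_s) / sqrt(nrow(d)) else 0,
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
    rownames(gs) <- NULL
    injury <- ifelse(grepl("^FPI", sm$group), "FPI", "Sham")
    stress <- ifelse(grepl("noStress$", sm$group), "noStress", "Stress")
    stats <- if (length(unique(sm$group)) < 2) {
      NULL  # single group: summary only, nothing to compare
    } else {
      list(
        t_injury = if (length(unique(injury)) == 2)
          t_two_sample(sm$mean_s[injury == "FPI"],
                       sm$mean_s[injury == "Sham"]) else NULL,
        t_stress = if (length(unique(stress)) == 2)
          t_two_sample(sm$mean_s[stress == "Stress"],
                       sm$mean_s[stress == "noStress"]) else NULL,
        anova = if (length(unique(injury)) == 2 &&
                      length(unique(stress)) == 2)
          anova_two_way(sm$mean_s, injury, stress) else NULL)
    }
    res[[regime]] <- list(subject_means = sm, group_summary = gs,
                          stats = stats)
  }
  res
}

#' Replicated cross-over experiments
#'
#' Runs [crossover_experiment()] on `n_reps` independently generated
#' cohorts (seeds `seed + r`) and collects the per-replicate ANOVA p values
#' together with the durations pooled across replicates. Headline claims
#' about training-condition parity are made on these replicate aggregates,
#' not on a single cohort.
#'
#' @param config a [cohort_config()] containing early and late seizures.
#' @param n_reps number of replicate cohorts.
#' @param img_cfg [image_config()].
#' @param seed master seed.
#' @param detector_args passed to [train_detector()].
#' @return list with `p_values` (data.frame `rep`, `p_training`, `p_class`,
#'   `p_interaction`), `durations` (pooled, with a `rep` column) and
#'   `cell_means` (pooled over replicates).
#' @export
crossover_replicates <- function(config, n_reps = 10,
                                 img_cfg = image_config(), seed = 1,
                                 detector_args = list()) {
  pv <- list(); durs <- list()
  for (r in seq_len(n_reps)) {
    co <- gen_cohort(config, seed = seed + r)
    res <- crossover_experiment(co, img_cfg = img_cfg,
                                seed = derive_seed(seed + r, "xover"),
                                detector_args = detector_args)
    tab <- res$anova$table
    pv[[r]] <- data.frame(rep = r,
                          p_training = tab$p[tab$term == "A"],
                          p_class = tab$p[tab$term == "B"],
                          p_interaction = tab$p[tab$term == "A:B"])
    durs[[r]] <- cbind(rep = r, res$durations)
  }
  durations <- do.call(rbind, durs)
  list(p_values = do.call(rbind, pv), durations = durations,
       cell_means = stats::aggregate(total_detected_s ~ training + test_class,
                                     durations, mean))
}

#' Ground-truth per-interval event durations (classifier-free path)
#'
#' Sums annotated event seconds per `(subject, interval)` directly from the
#' generator's ground truth — the fast path for calibration studies that do
#' not involve the classifier.
#'
#' @param cohort an `eeg_cohort`.
#' @param kind `"swd"` or `"seizure"`.
#' @return data.frame `subject_id`, `group`, `interval_index`,
#'   `latency_days`, `total_s` (zero-event intervals included).
#' @export
ground_truth_durations <- function(cohort, kind = c("swd", "seizure")) {
  kind <- match.arg(kind)
  ann <- cohort$annotations
  ann <- ann[ann$klass == kind, , drop = FALSE]
  man <- cohort$manifest$subjects
  do.call(rbind, lapply(man$subject_id, function(sid) {
    iv <- cohort$subjects[[sid]]$intervals
    tot <- vapply(iv$interval_index, function(ii) {
      sum(ann$duration_s[ann$subject_id == sid & ann$interval_index == ii])
    }, numeric(1))
    data.frame(subject_id = sid, group = man$group[match(sid, man$subject_id)],
               interval_index = iv$interval_index,
               latency_days = iv$latency_days, total_s = tot,
               stringsAsFactors = FALSE)
  }))
}

#' Null calibration of the group-difference test over replicate cohorts
#'
#' Generates `n_reps` independent cohorts from the same configuration (which
#' uses identical SWD generators in all four groups), computes per-subject
#' mean ground-truth SWD seconds per interval, and runs the two-way
#' injury x stress ANOVA on each replicate. Under this null the main-effect
#' p values are uniform, so rejections occur at about the alpha rate.
#'
#' @param config a [cohort_config()].
#' @param n_reps number of replicate cohorts.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param alpha rejection level.
#' @return list with `p_injury`, `p_stress` (vectors) and the rejection
#'   rates `rate_injury`, `rate_stress`.
#' @export
swd_null_calibration <- function(config = cohort_config(), n_reps = 200,
                                 seed = 1, alpha = 0.05) {
  p_inj <- p_str <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    co <- gen_cohort(config, seed = seed + r)
    gt <- ground_truth_durations(co, "swd")
    sm <- stats::aggregate(total_s ~ subject_id + group, gt, mean)
    injury <- ifelse(grepl("^FPI", sm$group), "FPI", "Sham")
    stress <- ifelse(grepl("noStress$", sm$group), "noStress", "Stress")
    a <- anova_two_way(sm$total_s, injury, stress)
    p_inj[r] <- a$table$p[a$table$term == "A"]
    p_str[r] <- a$table$p[a$table$term == "B"]
  }
  list(p_injury = p_inj, p_stress = p_str,
       rate_injury = mean(p_inj < alpha), rate_stress = mean(p_str < alpha))
}

#' Cohort-level incidence proportions
#'
#' @param pte_flags logical (or `"PTE"`/`"non-PTE"`) vector, one per subject.
#' @param seizure_flags optional logical vector: subject had any seizure.
#' @return list with counts and percentages (one decimal).
#' @export
incidence_report <- function(pte_flags, seizure_flags = NULL) {
  if (length(pte_flags) == 0) stop_arg("empty cohort")
  if (is.character(pte_flags)) pte_flags <- pte_flags == "PTE"
  out <- list(n_subjects = length(pte_flags),
              n_pte = sum(pte_flags),
              pte_incidence_pct = round(100 * mean(pte_flags), 1))
  if (!is.null(seizure_flags)) {
    out$n_with_seizures <- sum(seizure_flags)
    out$seizure_fraction_pct <- round(100 * mean(seizure_flags), 1)
  }
  out
}
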