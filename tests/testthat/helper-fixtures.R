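# Shared fixtures, built lazily and cached for the whole test session.
# Scaled study conditions: 250 Hz sampling, 48-frequency scalograms rendered
# at 32 px, small CNN; see the methods vignette for the rationale.

.fix <- new.env()

scaled_img_cfg <- function() image_config(n_freqs = 48, height = 32, width = 32)

# Enough optimizer steps that correctly separated posteriors saturate past
# the 0.99 detection threshold even with very small example pools.
fast_detector_args <- function() list(epochs = 60, batch_size = 8)

# Four-subject single-group cohort with early seizures only; detector
# trained on subject 1, evaluated on subjects 2-4. Used by the portability,
# partial-epoch, disjointness and threshold-monotonicity checks.
seizure_world <- function() {
  if (!is.null(.fix$world)) return(.fix$world)
  cfg <- cohort_config(n_per_group = 4, groups = "FPI_Stress",
                       n_days = 2, intervals_per_day = 2, fs = 250,
                       pte_fraction = 0, p_early = 1, n_early_mean = 3)
  cohort <- gen_cohort(cfg, seed = 101)
  icfg <- scaled_img_cfg()
  train_subj <- names(cohort$subjects)[1]
  test_subj <- names(cohort$subjects)[-1]
  ts <- make_training_set(cohort, "seizure", subjects = train_subj,
                          img_cfg = icfg, seed = 11)
  model <- do.call(train_detector,
                   c(list(ts, img_cfg = icfg, seed = 12), fast_detector_args()))
  preds <- detect_events(model, cohort, subjects = test_subj)
  .fix$world <- list(cohort = cohort, icfg = icfg, model = model,
                     train_subj = train_subj, test_subj = test_subj,
                     preds = preds,
                     eval = evaluate_detections(preds, cohort$annotations,
                                                klass = "seizure"))
  .fix$world
}

# SWD detector trained on the same cohort (SWDs are present everywhere;
# all subjects contribute examples, which also enriches the seizure
# hard-negative pool that keeps the two detection sets disjoint).
swd_model_for_world <- function() {
  if (!is.null(.fix$swd_model)) return(.fix$swd_model)
  w <- seizure_world()
  ts <- make_training_set(w$cohort, "swd", img_cfg = w$icfg, seed = 21)
  .fix$swd_model <- do.call(train_detector,
                            c(list(ts, img_cfg = w$icfg, seed = 22),
                              fast_detector_args()))
  .fix$swd_model
}

# Tiny equal-size toy images: bright (event) vs dark (background).
toy_training_set <- function(n = 10, size = 16, kind = "seizure", seed = 1) {
  set.seed(seed)
  ev <- lapply(seq_len(n), function(i) array(runif(size * size * 3, 0.6, 1),
                                             c(size, size, 3)))
  bg <- lapply(seq_len(n), function(i) array(runif(size * size * 3, 0, 0.4),
                                             c(size, size, 3)))
  training_set(ev, bg, event_kind = kind)
}

expect_sorted <- function(x) expect_true(!is.unsorted(x))
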