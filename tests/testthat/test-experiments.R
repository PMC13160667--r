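# Experiment harness units: ground-truth paths, incidence, null replication.
# Full classifier-based experiments run in test-acceptance.R.

test_that("ground-truth durations sum the annotations per interval", {
  cfg <- cohort_config(n_per_group = 1, n_days = 2, intervals_per_day = 2,
                       fs = 250, pte_fraction = 0, p_early = 0)
  co <- gen_cohort(cfg, seed = 21)
  gt <- ground_truth_durations(co, "swd")
  expect_equal(nrow(gt), 4 * 4)  # 4 subjects x 4 intervals, zeros included
  expect_equal(sum(gt$total_s),
               sum(co$annotations$duration_s[co$annotations$klass == "swd"]))
  one <- gt[gt$subject_id == "FPI_Stress_01" & gt$interval_index == 0, ]
  ann <- co$annotations
  expect_equal(one$total_s,
               sum(ann$duration_s[ann$subject_id == "FPI_Stress_01" &
                                    ann$interval_index == 0 &
                                    ann$klass == "swd"]))
})

test_that("incidence proportions report counts and rounded percentages", {
  rep5 <- incidence_report(c(rep(TRUE, 5), rep(FALSE, 56)))
  expect_equal(rep5$n_subjects, 61L)
  expect_equal(rep5$n_pte, 5L)
  expect_equal(rep5$pte_incidence_pct, 8.2)  # 5/61 to one decimal
  none <- incidence_report(rep("non-PTE", 10))
  expect_equal(none$pte_incidence_pct, 0)
  both <- incidence_report(c(TRUE, FALSE), seizure_flags = c(TRUE, TRUE))
  expect_equal(both$seizure_fraction_pct, 100)
  expect_error(incidence_report(logical(0)), "empty")
})

test_that("null calibration returns uniform-ish p values in small runs", {
  cfg <- cohort_config(n_per_group = 2, n_days = 1, intervals_per_day = 2,
                       fs = 250, pte_fraction = 0, p_early = 0)
  cal <- swd_null_calibration(cfg, n_reps = 8, seed = 99)
  expect_length(cal$p_injury, 8L)
  expect_true(all(cal$p_injury >= 0 & cal$p_injury <= 1))
  expect_true(all(cal$p_stress >= 0 & cal$p_stress <= 1))
})

test_that("the SWD group experiment summarizes a single group without tests", {
  cfg <- cohort_config(n_per_group = 2, groups = "FPI_Stress",
                       n_days = 7, intervals_per_day = 1, fs = 250,
                       pte_fraction = 0.5, p_early = 0)
  co <- gen_cohort(cfg, seed = 41)
  icfg <- image_config(n_freqs = 24, height = 24, width = 24)
  res <- swd_group_experiment(co, img_cfg = icfg, intervals_per_subject = 1,
                              seed = 42, detector_args = list(epochs = 8))
  expect_setequal(names(res), c("all_swd", "pte_swd_only"))
  for (r in res) {
    expect_equal(nrow(r$group_summary), 1L)
    expect_equal(r$group_summary$group, "FPI_Stress")
    expect_equal(r$group_summary$n, 2L)
    expect_null(r$stats)
  }
})

test_that("without PTE subjects the PTE-trained regime is skipped with a log", {
  cfg <- cohort_config(n_per_group = 1, n_days = 1, intervals_per_day = 2,
                       fs = 250, pte_fraction = 0, p_early = 0)
  co <- gen_cohort(cfg, seed = 51)
  icfg <- image_config(n_freqs = 24, height = 24, width = 24)
  msgs <- testthat::capture_messages(
    res <- swd_group_experiment(co, img_cfg = icfg, intervals_per_subject = 1,
                                seed = 52, detector_args = list(epochs = 8)))
  expect_true(any(grepl("skipping", msgs)))
  expect_identical(names(res), "all_swd")
  gs <- res$all_swd$group_summary
  expect_equal(nrow(gs), 4L)
  expect_true(all(gs$sem_s >= 0))
  expect_false(is.null(res$all_swd$stats$anova))
})

test_that("an injected group frequency shift is detectable (positive control)", {
  icfg <- scaled_img_cfg()
  mk_epoch <- function(f0r, seed) {
    sw <- gen_swd(swd_params(f0_range = f0r), fs = 250, seed = seed,
                  duration_s = 8)
    bg <- gen_background(10, 250, seed = seed + 5000)
    bg[251:2250] <- 0.4 * bg[251:2250] + sw$waveform
    scalodetect:::epoch_image(bg, 250, icfg)
  }
  ev <- lapply(1:10, function(i) mk_epoch(c(7, 8), 100 + i))
  bg <- lapply(1:15, function(i) {
    scalodetect:::epoch_image(gen_background(10, 250, seed = 200 + i),
                              250, icfg)
  })
  m <- train_detector(training_set(ev, bg, event_kind = "swd"),
                      img_cfg = icfg, seed = 3, epochs = 25)
  same <- vapply(1:8, function(i) {
    predict(m, list(mk_epoch(c(7, 8), 300 + i)))$confidence
  }, numeric(1))
  shifted <- vapply(1:8, function(i) {
    predict(m, list(mk_epoch(c(11.5, 12), 400 + i)))$confidence
  }, numeric(1))
  # detections concentrate in the trained band; the shifted band is
  # systematically down-weighted
  expect_gte(sum(same > 0.99), 6L)
  expect_lte(sum(shifted > 0.99), 2L)
  expect_gt(mean(same) - mean(shifted), 0.1)
})

test_that("unknown training subsets are rejected", {
  expect_error(scalodetect:::train_subset_args("bogus"), "unknown")
})

test_that("a cohort without seizures cannot run the crossover design", {
  cfg <- cohort_config(n_per_group = 1, n_days = 1, intervals_per_day = 1,
                       fs = 250, pte_fraction = 0, p_early = 0)
  co <- gen_cohort(cfg, seed = 31)
  expect_error(crossover_experiment(co), "no seizures")
})
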