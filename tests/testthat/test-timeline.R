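# Detection aggregation: per-interval totals, runs, timelines, PTE calls.

pred_df <- function(event_epochs, n = 180, sid = "r1", ii = 0L) {
  data.frame(subject_id = sid, interval_index = ii,
             epoch_index = 0:(n - 1),
             label = ifelse(0:(n - 1) %in% event_epochs, "event", "background"),
             confidence = ifelse(0:(n - 1) %in% event_epochs, 0.999, 0.01),
             stringsAsFactors = FALSE)
}

test_that("ten flagged epochs aggregate to 100 s of detected activity", {
  agg <- aggregate_interval(pred_df(10:19))
  expect_equal(agg$total_detected_s, 100)
  expect_equal(nrow(agg$runs), 1L)
})

test_that("an empty interval aggregates to zero with no runs", {
  agg <- aggregate_interval(pred_df(integer(0)))
  expect_equal(agg$total_detected_s, 0)
  expect_equal(nrow(agg$runs), 0L)
})

test_that("separated blocks form distinct maximal runs (brute-force case)", {
  agg <- aggregate_interval(pred_df(c(3, 4, 5, 90, 91)))
  expect_equal(agg$total_detected_s, 50)
  expect_equal(agg$runs$first_epoch, c(3L, 90L))
  expect_equal(agg$runs$last_epoch, c(5L, 91L))
  # conservation: run lengths x 10 s sum to the interval total
  expect_equal(10 * sum(agg$runs$n_epochs), agg$total_detected_s)
  # duplicate epochs are rejected
  bad <- rbind(pred_df(1), pred_df(1)[1, ])
  expect_error(aggregate_interval(bad), "duplicate")
})

test_that("run merging across a one-epoch gap is available but off by default", {
  p <- pred_df(c(10, 11, 13, 14))  # undetected MID epoch at 12
  expect_equal(nrow(aggregate_interval(p)$runs), 2L)
  merged <- aggregate_interval(p, merge_gap_epochs = 1L)
  expect_equal(nrow(merged$runs), 1L)
  expect_equal(merged$total_detected_s, 40)  # totals unaffected by merging
})

test_that("timelines hold one sorted entry per detected interval", {
  preds <- rbind(pred_df(1:3, ii = 0L), pred_df(integer(0), ii = 1L),
                 pred_df(c(5, 50, 100), ii = 2L))
  lat <- data.frame(interval_index = 0:2, latency_days = c(3, 1, 2))
  tl <- build_timeline(preds, lat)
  expect_equal(nrow(tl), 2L)
  expect_sorted(tl$latency_days)
  expect_equal(tl$total_detected_s[tl$interval_index == 2], 30)
  expect_equal(tl$n_runs[tl$interval_index == 2], 3L)  # cluster flag
  expect_error(build_timeline(preds, lat[1:2, ]), "missing latency")
  # no detections anywhere -> empty timeline
  empty <- build_timeline(pred_df(integer(0)), lat)
  expect_equal(nrow(empty), 0L)
})

test_that("timelines are invariant to prediction row order", {
  preds <- pred_df(c(17, 18, 60))
  lat <- data.frame(interval_index = 0L, latency_days = 1.5)
  shuffled <- preds[sample.int(nrow(preds)), ]
  expect_equal(build_timeline(shuffled, lat), build_timeline(preds, lat))
})

test_that("the early/late boundary sits at exactly 5 days", {
  expect_equal(classify_latency(c(0, 5, 5.01, 200)),
               c("early", "early", "late", "late"))
  expect_error(classify_latency(-0.1), ">= 0")
})

test_that("duration summaries report mean, SEM and the n=1 degenerate case", {
  tl <- data.frame(total_detected_s = c(40, 60))
  s <- summarize_detection_durations(tl)
  expect_equal(s$mean_s, 50)
  expect_equal(s$sem_s, 10)
  one <- summarize_detection_durations(data.frame(total_detected_s = 100))
  expect_equal(one$mean_s, 100)
  expect_equal(one$sem_s, 0)
  expect_false(one$sem_defined)
  expect_error(summarize_detection_durations(data.frame(total_detected_s = numeric(0))),
               "no detection")
})

test_that("PTE requires at least one late detection run", {
  lat <- data.frame(interval_index = 0:1, latency_days = c(2, 8))
  late_run <- build_timeline(rbind(pred_df(1:2, ii = 0L), pred_df(7, ii = 1L)), lat)
  expect_equal(pte_status(late_run), "PTE")
  early_only <- build_timeline(rbind(pred_df(1:2, ii = 0L),
                                     pred_df(integer(0), ii = 1L)), lat)
  expect_equal(pte_status(early_only), "non-PTE")
  expect_equal(pte_status(late_run, threshold_late = 2), "non-PTE")
})

test_that("oracle predictions recover interval totals within boundary epochs", {
  prof <- subject_profile("FPI_Stress", n_early = 3)
  s <- gen_subject(prof, "r9", n_days = 1, intervals_per_day = 2, fs = 250,
                   seed = 33)
  ann <- s$annotations
  for (ii in unique(ann$interval_index[ann$klass == "seizure"])) {
    a <- ann[ann$interval_index == ii, ]
    # oracle: flag every epoch overlapping any annotated event
    flagged <- which(vapply(0:179, function(e) {
      any(scalodetect:::epoch_overlaps(e, a$start_s, a$duration_s, 10))
    }, logical(1))) - 1L
    agg <- aggregate_interval(pred_df(flagged, sid = "r9", ii = ii))
    true_s <- sum(a$duration_s)
    expect_lte(abs(agg$total_detected_s - true_s), 20 * length(unique(a$event_id)))
  }
})
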