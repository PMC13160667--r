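# Classifier contracts: splitting, training, detection rule, corrections,
# evaluation. Heavier cross-subject runs live in test-acceptance.R.

test_that("train/validation splits are stratified, disjoint and seeded", {
  ts <- toy_training_set(n = 30, seed = 1)
  sp <- split_train_val(ts, 0.5, seed = 2)
  expect_equal(sum(sp$train$labels == "event"), 15L)
  expect_equal(sum(sp$train$labels == "background"), 15L)
  expect_equal(length(sp$val$labels), 30L)
  sp2 <- split_train_val(ts, 0.5, seed = 2)
  expect_identical(sp$train$labels, sp2$train$labels)
  expect_identical(sp$train$images, sp2$train$images)
  expect_warning(full <- split_train_val(ts, 1, seed = 3), "empty")
  expect_length(full$val$labels, 0L)
  tiny <- training_set(ts$images[1], ts$images[31:32], event_kind = "seizure")
  expect_error(split_train_val(tiny, 0.5), "fewer than 2")
})

test_that("training sets validate class presence and image sizes", {
  imgs <- lapply(1:4, function(i) array(0.5, c(8, 8, 3)))
  expect_error(training_set(imgs, list(), "seizure"), "both classes")
  expect_error(training_set(imgs, list(array(0, c(4, 4, 3))), "seizure"),
               "uniform")
})

test_that("a separable toy problem reaches validation accuracy 1", {
  ts <- toy_training_set(n = 12, seed = 4)
  m <- train_detector(ts, epochs = 30, seed = 5, channels = c(4, 8))
  expect_equal(m$metadata$val_accuracy, 1)
  expect_true(m$metadata$converged)
})

test_that("training is deterministic for identical seed and data", {
  ts <- toy_training_set(n = 6, size = 12, seed = 6)
  m1 <- train_detector(ts, epochs = 4, seed = 7, channels = c(4, 8))
  m2 <- train_detector(ts, epochs = 4, seed = 7, channels = c(4, 8))
  expect_identical(m1$net$layers, m2$net$layers)
  m3 <- train_detector(ts, epochs = 4, seed = 8, channels = c(4, 8))
  expect_false(identical(m1$net$layers, m3$net$layers))
})

test_that("prediction enforces the image-size contract and threshold rule", {
  ts <- toy_training_set(n = 8, size = 12, seed = 9)
  m <- train_detector(ts, epochs = 8, seed = 10, channels = c(4, 8))
  pr <- predict(m, ts$images)
  expect_equal(nrow(pr), 16L)
  expect_identical(pr$label, ifelse(pr$confidence > m$threshold,
                                    "event", "background"))
  expect_true(all(pr$confidence >= 0 & pr$confidence <= 1))
  expect_error(predict(m, list(array(0, c(6, 6, 3)))), "size mismatch")
  expect_error(train_detector(ts, threshold = 0.4), "threshold")
})

test_that("lowering the threshold never shrinks the detected set", {
  ts <- toy_training_set(n = 10, size = 12, seed = 11)
  m <- train_detector(ts, epochs = 8, seed = 12, channels = c(4, 8))
  hi <- predict(m, ts$images)
  m$threshold <- 0.6
  lo <- predict(m, ts$images)
  expect_true(all(which(hi$label == "event") %in% which(lo$label == "event")))
})

test_that("classify_segments yields one ordered prediction per epoch", {
  rec <- eeg_record(gen_background(60, 250, seed = 13), fs = 250,
                    subject_id = "ratC")
  eps <- segment_record(rec, interval_index = 4L)
  icfg <- image_config(n_freqs = 24, height = 12, width = 12)
  ts <- toy_training_set(n = 6, size = 12, seed = 14)
  m <- train_detector(ts, epochs = 3, seed = 15, img_cfg = icfg, channels = c(4, 8))
  pr <- classify_segments(m, eps)
  expect_equal(nrow(pr), 6L)
  expect_identical(pr$epoch_index, 0:5)
  expect_identical(unique(pr$subject_id), "ratC")
  expect_identical(unique(pr$interval_index), 4L)
})

test_that("correction retraining grows the pools and is a no-op when empty", {
  ts <- toy_training_set(n = 6, size = 12, seed = 16)
  m <- train_detector(ts, epochs = 3, seed = 17, channels = c(4, 8))
  expect_identical(retrain_with_corrections(m), m)
  fps <- lapply(1:8, function(i) array(runif(12 * 12 * 3), c(12, 12, 3)))
  m2 <- retrain_with_corrections(m, false_positive_images = fps)
  expect_equal(sum(m2$pools$labels == "background"),
               sum(m$pools$labels == "background") + 8L)
  expect_equal(sum(m2$pools$labels == "event"), sum(m$pools$labels == "event"))
  expect_equal(m2$metadata$correction_iteration, 1L)
})

test_that("evaluation scores hand-built overlap cases correctly", {
  ann <- data.frame(subject_id = "r", interval_index = 0L, latency_days = 1,
                    event_id = c("e1", "e2", "e3"), klass = "seizure",
                    phase = "sz_onset", start_s = c(100, 600, 1200),
                    duration_s = c(50, 30, 40), latency_class = "early",
                    stringsAsFactors = FALSE)
  mk_preds <- function(event_epochs) {
    data.frame(subject_id = "r", interval_index = 0L, epoch_index = 0:179,
               label = ifelse(0:179 %in% event_epochs, "event", "background"),
               confidence = 0.999, stringsAsFactors = FALSE)
  }
  # epochs covering events 1 and 2 only -> sensitivity 2/3
  part <- evaluate_detections(mk_preds(c(10, 60)), ann)
  expect_equal(part$sensitivity, 2 / 3)
  # oracle predictions: all three events hit, no false positives
  oracle <- evaluate_detections(mk_preds(c(10, 60, 120)), ann)
  expect_equal(oracle$sensitivity, 1)
  expect_equal(oracle$fp_count, 0L)
  expect_equal(oracle$specificity, 1)
  # all-background predictions
  none <- evaluate_detections(mk_preds(integer(0)), ann)
  expect_equal(none$sensitivity, 0)
  # a flagged epoch overlapping nothing is a false positive
  fp <- evaluate_detections(mk_preds(c(10, 60, 120, 170)), ann)
  expect_equal(fp$fp_count, 1L)
  expect_lt(fp$specificity, 1)
  # mismatched subjects are an error
  bad <- mk_preds(10); bad$subject_id <- "other"
  expect_error(evaluate_detections(bad, ann), "no subject ids")
})
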