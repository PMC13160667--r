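# Detector training and application: event-vs-background classification of
# scalogram images at a fixed confidence threshold.

#' Scalogram image configuration
#'
#' Bundles the epoch-to-image settings a detector was trained with, so the
#' same transform is applied at detection time. Defaults follow the rendered
#' figure conventions (96 log-spaced frequencies over 1-100 Hz); tests and
#' the experiment harness use the smaller scaled sizes documented in the
#' methods vignette.
#'
#' @param n_freqs frequency rows of the scalogram.
#' @param freq_range frequency span, Hz.
#' @param omega0 Morlet center-frequency parameter.
#' @param height,width rendered image size, pixels.
#' @param colormap,scaling see [render_scalogram()].
#' @return an object of class `image_config`.
#' @export
image_config <- function(n_freqs = 96, freq_range = c(1, 100), omega0 = 6,
                         height = 64, width = 64, colormap = "viridis",
                         scaling = "per_image") {
  structure(as.list(environment()), class = "image_config")
}

epoch_image <- function(x, fs, cfg) {
  scal <- cwt_scalogram(x, fs, n_freqs = cfg$n_freqs,
                        freq_range = cfg$freq_range, omega0 = cfg$omega0)
  render_scalogram(scal, height = cfg$height, width = cfg$width,
                   colormap = cfg$colormap, scaling = cfg$scaling)
}

#' Assemble a labeled scalogram training set
#'
#' @param event_images list of event-class images (equal-sized arrays).
#' @param background_images list of background-class images.
#' @param event_kind `"seizure"` or `"swd"`.
#' @param provenance optional character vector of annotation/event ids.
#' @return an object of class `training_set`.
#' @export
training_set <- function(event_images, background_images,
                         event_kind = c("seizure", "swd"),
                         provenance = NULL) {
  event_kind <- match.arg(event_kind)
  if (length(event_images) == 0 || length(background_images) == 0) {
    stop_arg("both classes must be present in a training set")
  }
  dims <- unique(lapply(c(event_images, background_images), dim))
  if (length(dims) != 1L) stop_arg("images must have uniform size")
  structure(list(images = c(event_images, background_images),
                 labels = rep(c("event", "background"),
                              c(length(event_images), length(background_images))),
                 event_kind = event_kind, provenance = provenance,
                 image_dim = dims[[1]]),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %s: %d event + %d background images (%s)\n",
              x$event_kind, sum(x$labels == "event"),
              sum(x$labels == "background"),
              paste(x$image_dim, collapse = "x")))
  invisible(x)
}

subset_training_set <- function(ts, idx) {
  structure(list(images = ts$images[idx], labels = ts$labels[idx],
                 event_kind = ts$event_kind,
                 provenance = ts$provenance[idx], image_dim = ts$image_dim),
            class = "training_set")
}

#' Stratified train/validation split
#'
#' Randomly assigns `fraction` of each class to training and the remainder
#' to validation (half and half by default). Reproducible for a given seed.
#'
#' @param ts a [training_set()].
#' @param fraction training fraction in (0, 1\]; `fraction = 1` yields an
#'   empty validation set with a warning.
#' @param seed integer seed.
#' @return list with `train` and `val` training sets.
#' @export
split_train_val <- function(ts, fraction = 0.5, seed = NULL) {
  stopifnot(inherits(ts, "training_set"))
  for (cl in c("event", "background")) {
    if (sum(ts$labels == cl) < 2L) {
      stop_arg("class '", cl, "' has fewer than 2 items")
    }
  }
  if (fraction <= 0 || fraction > 1) stop_arg("`fraction` must be in (0, 1]")
  if (fraction == 1) warning("fraction = 1: validation set is empty")
  with_seed(seed, {
    tr_idx <- unlist(lapply(c("event", "background"), function(cl) {
      idx <- which(ts$labels == cl)
      sample(idx, round(fraction * length(idx)))
    }))
    list(train = subset_training_set(ts, sort(tr_idx)),
         val = subset_training_set(ts, setdiff(seq_along(ts$labels), tr_idx)))
  })
}

#' Train an event detector on scalogram images
#'
#' Splits the labeled pool into training and validation halves (stratified),
#' balances the background pool to the event pool size, trains the small
#' CNN, and fixes the detection rule: an epoch is flagged as an event iff
#' the softmax posterior of the event class strictly exceeds `threshold`
#' (default 0.99). If validation accuracy stays below 0.6 the model is
#' flagged `converged = FALSE` in its metadata rather than erroring.
#'
#' @param ts a [training_set()].
#' @param threshold detection confidence threshold in (0.5, 1).
#' @param split_fraction training fraction of the pools.
#' @param epochs,lr,batch_size optimizer settings (Adam).
#' @param channels conv-layer widths of the backbone.
#' @param balance_classes subsample the background pool to the event pool
#'   size before training.
#' @param img_cfg the [image_config()] used to build the images; stored so
#'   detection applies the identical transform.
#' @param seed integer seed (weights, split, batching).
#' @return an object of class `eeg_detector`.
#' @export
train_detector <- function(ts, threshold = 0.99, split_fraction = 0.5,
                           epochs = 30, lr = 3e-3, batch_size = 8,
                           channels = c(8, 16, 32),
                           balance_classes = TRUE,
                           img_cfg = NULL, seed = 1) {
  stopifnot(inherits(ts, "training_set"))
  if (threshold <= 0.5 || threshold >= 1) {
    stop_arg("`threshold` must be in (0.5, 1)")
  }
  sp <- split_train_val(ts, split_fraction, seed = derive_seed(seed, "split"))
  tr <- sp$train
  if (balance_classes) {
    ev <- which(tr$labels == "event"); bg <- which(tr$labels == "background")
    if (length(bg) > length(ev)) {
      keep <- with_seed(derive_seed(seed, "balance"),
                        sample(bg, length(ev)))
      tr <- subset_training_set(tr, sort(c(ev, keep)))
    }
  }
  y <- ifelse(tr$labels == "event", 2L, 1L)
  net <- cnn_init(tr$image_dim, channels = channels,
                  seed = derive_seed(seed, "init"))
  net <- cnn_train_loop(net, tr$images, y, epochs = epochs, lr = lr,
                        batch_size = batch_size,
                        seed = derive_seed(seed, "batches"))
  val_acc <- NA_real_
  if (length(sp$val$labels) > 0) {
    p <- cnn_predict_probs(net, sp$val$images)
    val_acc <- mean((p[, 2] > 0.5) == (sp$val$labels == "event"))
  }
  structure(list(net = net, threshold = threshold,
                 event_kind = ts$event_kind,
                 class_levels = c("background", "event"),
                 pools = ts,  # full labeled pools, kept for correction loops
                 img_cfg = img_cfg,
                 metadata = list(seed = seed, epochs = epochs, lr = lr,
                                 batch_size = batch_size, channels = channels,
                                 split_fraction = split_fraction,
                                 val_accuracy = val_acc,
                                 converged = is.na(val_acc) || val_acc >= 0.6,
                                 correction_iteration = 0L)),
            class = "eeg_detector")
}

#' @export
print.eeg_detector <- function(x, ...) {
  cat(sprintf("<eeg_detector> %s vs background; threshold > %g\n",
              x$event_kind, x$threshold))
  cat(sprintf("  pools: %d event / %d background; val accuracy %.3f%s; correction iter %d\n",
              sum(x$pools$labels == "event"),
              sum(x$pools$labels == "background"),
              x$metadata$val_accuracy,
              if (x$metadata$converged) "" else " (NOT converged)",
              x$metadata$correction_iteration))
  invisible(x)
}

#' @export
predict.eeg_detector <- function(object, images, ...) {
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1L || !identical(dims[[1]], object$pools$image_dim)) {
    stop_arg("image size mismatch: detector expects ",
             paste(object$pools$image_dim, collapse = "x"))
  }
  p <- cnn_predict_probs(object$net, images)
  data.frame(label = ifelse(p[, 2] > object$threshold, "event", "background"),
             confidence = p[, 2], stringsAsFactors = FALSE)
}

#' Classify the epochs of one interval
#'
#' Converts every epoch to a scalogram image with the detector's stored
#' image configuration and applies the fixed-threshold detection rule.
#' Order-preserving: one prediction per epoch.
#'
#' @param model an `eeg_detector`.
#' @param epochs an `epoch_set` from [segment_record()].
#' @return data.frame with columns `subject_id`, `interval_index`,
#'   `epoch_index`, `label`, `confidence`.
#' @export
classify_segments <- function(model, epochs) {
  stopifnot(inherits(model, "eeg_detector"), inherits(epochs, "epoch_set"))
  cfg <- model$img_cfg %||% image_config()
  imgs <- epochs_to_images(epochs, n_freqs = cfg$n_freqs,
                           freq_range = cfg$freq_range, omega0 = cfg$omega0,
                           height = cfg$height, width = cfg$width,
                           colormap = cfg$colormap, scaling = cfg$scaling)
  pr <- predict(model, imgs)
  data.frame(subject_id = epochs$subject_id,
             interval_index = epochs$interval_index,
             epoch_index = epochs$epoch_index,
             label = pr$label, confidence = pr$confidence,
             stringsAsFactors = FALSE)
}

#' Correction-loop retraining
#'
#' Appends reviewed false-positive epochs to the background pool and missed
#' events to the event pool, then retrains from the enlarged pools. With no
#' corrections the input model is returned unchanged.
#'
#' @param model an `eeg_detector`.
#' @param false_positive_images images wrongly flagged as events.
#' @param missed_event_images event images the detector missed.
#' @param seed seed for the retraining run (defaults to the model's).
#' @return a retrained `eeg_detector` with `correction_iteration`
#'   incremented.
#' @export
retrain_with_corrections <- function(model, false_positive_images = list(),
                                     missed_event_images = list(),
                                     seed = NULL) {
  stopifnot(inherits(model, "eeg_detector"))
  if (length(false_positive_images) == 0 && length(missed_event_images) == 0) {
    return(model)
  }
  pools <- model$pools
  ts <- training_set(
    event_images = c(pools$images[pools$labels == "event"], missed_event_images),
    background_images = c(pools$images[pools$labels == "background"],
                          false_positive_images),
    event_kind = model$event_kind)
  md <- model$metadata
  out <- train_detector(ts, threshold = model$threshold,
                        split_fraction = md$split_fraction,
                        epochs = md$epochs, lr = md$lr,
                        batch_size = md$batch_size, channels = md$channels,
                        img_cfg = model$img_cfg,
                        seed = seed %||% (md$seed + 1L))
  out$metadata$correction_iteration <- md$correction_iteration + 1L
  out
}

# epoch span helper: half-open [start, start + epoch_s)
epoch_overlaps <- function(epoch_index, ann_start, ann_dur, epoch_s) {
  ep0 <- epoch_index * epoch_s
  ep0 < (ann_start + ann_dur) & (ep0 + epoch_s) > ann_start
}

#' Score predictions against ground-truth annotations
#'
#' Event-level sensitivity: an annotated event counts as detected iff at
#' least one epoch overlapping it is labeled as an event. Segment-level
#' specificity: fraction of epochs overlapping no annotation that are
#' labeled background. False positives are event-labeled epochs overlapping
#' no annotation.
#'
#' @param predictions data.frame from [classify_segments()] (possibly
#'   row-bound over intervals/subjects).
#' @param annotations ground-truth annotation data.frame (as produced by
#'   [gen_subject()]/[gen_cohort()]); filtered to `klass` if given.
#' @param klass restrict ground-truth events to this class (e.g.
#'   `"seizure"`); background epochs are still defined by overlap with *any*
#'   annotation.
#' @param epoch_s epoch length, seconds.
#' @return list with `sensitivity`, `specificity`, `fp_count`, `n_events`,
#'   `n_detected`, `n_background_epochs`.
#' @export
evaluate_detections <- function(predictions, annotations, klass = NULL,
                                epoch_s = 10) {
  if (nrow(annotations) > 0 &&
      length(intersect(unique(predictions$subject_id),
                       unique(annotations$subject_id))) == 0) {
    stop_arg("predictions and annotations share no subject ids")
  }
  target <- if (is.null(klass)) annotations else
    annotations[annotations$klass == klass, , drop = FALSE]
  # only events inside the predicted (subject, interval) scope are scorable
  scope <- unique(paste(predictions$subject_id, predictions$interval_index))
  target <- target[paste(target$subject_id, target$interval_index) %in% scope, ,
                   drop = FALSE]

  # per-event detection
  ev_ids <- unique(target$event_id)
  detected <- logical(length(ev_ids))
  for (i in seq_along(ev_ids)) {
    rows <- target[target$event_id == ev_ids[i], , drop = FALSE]
    lo <- min(rows$start_s); hi <- max(rows$start_s + rows$duration_s)
    pr <- predictions[predictions$subject_id == rows$subject_id[1] &
                        predictions$interval_index == rows$interval_index[1], ,
                      drop = FALSE]
    hit <- epoch_overlaps(pr$epoch_index, lo, hi - lo, epoch_s) &
      pr$label == "event"
    detected[i] <- any(hit)
  }

  # per-epoch background status (overlap with any annotation, any class)
  bg <- rep(TRUE, nrow(predictions))
  key <- paste(predictions$subject_id, predictions$interval_index)
  for (k in unique(key)) {
    sel <- which(key == k)
    ann <- annotations[paste(annotations$subject_id,
                             annotations$interval_index) == k, , drop = FALSE]
    if (nrow(ann) == 0) next
    for (j in seq_len(nrow(ann))) {
      bg[sel] <- bg[sel] & !epoch_overlaps(predictions$epoch_index[sel],
                                           ann$start_s[j], ann$duration_s[j],
                                           epoch_s)
    }
  }
  fp <- sum(bg & predictions$label == "event")
  list(sensitivity = if (length(ev_ids)) mean(detected) else NA_real_,
       specificity = if (any(bg)) mean(predictions$label[bg] == "background")
                     else NA_real_,
       fp_count = fp,
       n_events = length(ev_ids), n_detected = sum(detected),
       n_background_epochs = sum(bg))
}
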