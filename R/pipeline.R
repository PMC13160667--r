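# Glue between the synthetic cohort and the classifier: building labeled
# image pools from ground truth and streaming detection over intervals.
# Intervals are rendered on demand and never held in memory together.

ictal_span <- function(event_rows) {
  # span used to pick training epochs: ictal phases only (PID and trailing
  # bursts are not part of the seizure proper)
  ict <- event_rows[event_rows$phase %in% c("sz_onset", "mid", "sz_end", "whole"), ,
                    drop = FALSE]
  c(min(ict$start_s), max(ict$start_s + ict$duration_s))
}

#' Collect event-class scalogram images from a cohort
#'
#' Renders each interval containing a targeted event, segments it on the
#' fixed 10 s grid, and keeps for every event the epoch(s) with the largest
#' overlap — the programmatic analogue of visually selecting event examples.
#'
#' @param cohort an `eeg_cohort`.
#' @param kind `"seizure"` or `"swd"`.
#' @param subjects restrict to these subject ids (default all).
#' @param latency_class restrict seizures to `"early"` or `"late"`.
#' @param pte_only restrict to subjects with late seizures (PTE).
#' @param img_cfg an [image_config()].
#' @param max_per_event at most this many grid epochs per event.
#' @param augment_partial additionally render, for each event, one off-grid
#'   window in which the event occupies only the latter ~6 s, so the pool
#'   represents epochs partially covered by an event (default `TRUE` —
#'   detection runs on a fixed 10 s grid, and events rarely align with it).
#' @return list with `images` and `provenance` (event ids).
#' @export
collect_event_images <- function(cohort, kind = c("seizure", "swd"),
                                 subjects = NULL, latency_class = NULL,
                                 pte_only = FALSE,
                                 img_cfg = image_config(),
                                 max_per_event = 2L,
                                 augment_partial = TRUE) {
  kind <- match.arg(kind)
  ann <- cohort$annotations
  ann <- ann[ann$klass == kind, , drop = FALSE]
  if (!is.null(subjects)) ann <- ann[ann$subject_id %in% subjects, , drop = FALSE]
  if (pte_only) {
    pte <- cohort$manifest$subjects$subject_id[cohort$manifest$subjects$has_late]
    ann <- ann[ann$subject_id %in% pte, , drop = FALSE]
  }
  if (!is.null(latency_class)) {
    ann <- ann[!is.na(ann$latency_class) & ann$latency_class %in% latency_class, ,
               drop = FALSE]
  }
  images <- list(); prov <- character(0)
  epoch_s <- 10
  for (k in unique(paste(ann$subject_id, ann$interval_index))) {
    rows <- ann[paste(ann$subject_id, ann$interval_index) == k, , drop = FALSE]
    sid <- rows$subject_id[1]; ii <- rows$interval_index[1]
    rec <- cohort_record(cohort, sid, ii)
    eps <- segment_record(rec, epoch_s = epoch_s, interval_index = ii)
    for (eid in unique(rows$event_id)) {
      span <- ictal_span(rows[rows$event_id == eid, , drop = FALSE])
      ovl <- pmin(span[2], (eps$epoch_index + 1) * epoch_s) -
        pmax(span[1], eps$epoch_index * epoch_s)
      # epochs qualify as examples with >= 2.5 s of event content; the pool
      # mixes the best-covered epochs with one partially covered boundary
      # epoch per event, so partial-epoch detections are represented
      qual <- order(ovl, decreasing = TRUE)
      qual <- qual[ovl[qual] >= min(2.5, ovl[qual[1]])]
      take <- unique(c(qual[1], qual[length(qual)],
                       qual[-c(1, length(qual))]))[seq_len(min(max_per_event,
                                                               length(qual)))]
      for (t in take) {
        images[[length(images) + 1L]] <-
          epoch_image(eps$samples[t, ], eps$fs, img_cfg)
        prov <- c(prov, eid)
      }
      if (augment_partial) {
        i0 <- round(max(0, span[1] - 4) * rec$fs) + 1L
        i1 <- i0 + round(epoch_s * rec$fs) - 1L
        if (i1 <= length(rec$samples)) {
          images[[length(images) + 1L]] <-
            epoch_image(rec$samples[i0:i1], rec$fs, img_cfg)
          prov <- c(prov, eid)
        }
      }
    }
  }
  list(images = images, provenance = prov)
}

#' Collect background scalogram images from a cohort
#'
#' Samples epochs that overlap no ground-truth annotation of any class,
#' drawn from randomly chosen intervals.
#'
#' @param cohort an `eeg_cohort`.
#' @param n number of background images wanted.
#' @param img_cfg an [image_config()].
#' @param subjects restrict to these subject ids.
#' @param seed integer seed.
#' @return list of images.
#' @export
collect_background_images <- function(cohort, n, img_cfg = image_config(),
                                      subjects = NULL, seed = 1) {
  sel <- subjects %||% names(cohort$subjects)
  epoch_s <- 10
  with_seed(seed, {
    pairs <- do.call(rbind, lapply(sel, function(sid) {
      data.frame(subject_id = sid,
                 interval_index = cohort$subjects[[sid]]$intervals$interval_index,
                 stringsAsFactors = FALSE)
    }))
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    images <- list()
    for (r in seq_len(nrow(pairs))) {
      if (length(images) >= n) break
      sid <- pairs$subject_id[r]; ii <- pairs$interval_index[r]
      ann <- cohort$annotations
      ann <- ann[ann$subject_id == sid & ann$interval_index == ii, , drop = FALSE]
      rec <- cohort_record(cohort, sid, ii)
      eps <- segment_record(rec, epoch_s = epoch_s, interval_index = ii)
      free <- rep(TRUE, n_epochs(eps))
      for (j in seq_len(nrow(ann))) {
        free <- free & !epoch_overlaps(eps$epoch_index, ann$start_s[j],
                                       ann$duration_s[j], epoch_s)
      }
      pick <- sample(which(free), min(sum(free), ceiling(n / 4)))
      for (t in pick) {
        if (length(images) >= n) break
        images[[length(images) + 1L]] <-
          epoch_image(eps$samples[t, ], eps$fs, img_cfg)
      }
    }
    images
  })
}

#' Build a training set from cohort ground truth
#'
#' Convenience wrapper over [collect_event_images()] and
#' [collect_background_images()]; the background pool defaults to 1.5x the
#' event pool.
#'
#' @inheritParams collect_event_images
#' @param n_background background pool size (default `1.5 *` events).
#' @param background_subjects subjects to draw background from (defaults to
#'   `subjects`).
#' @param include_other_kind add epochs of the *other* event class to the
#'   background pool (default `TRUE`). A seizure detector must treat
#'   spike-wave discharges as background and vice versa, so the background
#'   pool represents the full variety of non-target EEG; without these hard
#'   negatives the two detection sets overlap.
#' @param seed integer seed.
#' @return a [training_set()].
#' @export
make_training_set <- function(cohort, kind = c("seizure", "swd"),
                              subjects = NULL, latency_class = NULL,
                              pte_only = FALSE, img_cfg = image_config(),
                              n_background = NULL, background_subjects = NULL,
                              include_other_kind = TRUE,
                              seed = 1, max_per_event = 2L) {
  kind <- match.arg(kind)
  ev <- collect_event_images(cohort, kind, subjects = subjects,
                             latency_class = latency_class,
                             pte_only = pte_only, img_cfg = img_cfg,
                             max_per_event = max_per_event)
  if (length(ev$images) == 0) stop_arg("no ", kind, " events match the selection")
  nb <- n_background %||% ceiling(1.5 * length(ev$images))
  hard <- list()
  if (include_other_kind) {
    other <- setdiff(c("seizure", "swd"), kind)
    hard <- tryCatch(
      collect_event_images(cohort, other,
                           subjects = background_subjects %||% subjects,
                           img_cfg = img_cfg, max_per_event = 1L)$images,
      error = function(e) list())
    cap <- ceiling(nb / 2)  # keep at least half the pool as quiet background
    if (length(hard) > cap) {
      hard <- hard[with_seed(derive_seed(seed, "hard"),
                             sample.int(length(hard), cap))]
    }
  }
  bg <- collect_background_images(cohort, max(nb - length(hard), 2L),
                                  img_cfg = img_cfg,
                                  subjects = background_subjects %||% subjects,
                                  seed = derive_seed(seed, "bg"))
  training_set(ev$images, c(bg, hard), event_kind = kind,
               provenance = ev$provenance)
}

#' Run a detector across cohort intervals
#'
#' Streams over the requested `(subject, interval)` pairs: renders each
#' interval, segments it into 10 s epochs, classifies every epoch, and
#' row-binds the predictions.
#'
#' @param model an `eeg_detector`.
#' @param cohort an `eeg_cohort`.
#' @param subjects subject ids (default all).
#' @param intervals optional data.frame with columns `subject_id`,
#'   `interval_index` restricting the scan.
#' @return prediction data.frame (see [classify_segments()]).
#' @export
detect_events <- function(model, cohort, subjects = NULL, intervals = NULL) {
  stopifnot(inherits(model, "eeg_detector"), inherits(cohort, "eeg_cohort"))
  if (is.null(intervals)) {
    sel <- subjects %||% names(cohort$subjects)
    intervals <- do.call(rbind, lapply(sel, function(sid) {
      data.frame(subject_id = sid,
                 interval_index = cohort$subjects[[sid]]$intervals$interval_index,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- vector("list", nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    rec <- cohort_record(cohort, intervals$subject_id[r],
                         intervals$interval_index[r])
    eps <- segment_record(rec, interval_index = intervals$interval_index[r])
    out[[r]] <- classify_segments(model, eps)
  }
  do.call(rbind, out)
}

#' Interval latency lookup for a cohort subject
#' @param cohort an `eeg_cohort`.
#' @param subject_id subject label.
#' @return data.frame `interval_index`, `latency_days`.
#' @export
interval_latency <- function(cohort, subject_id) {
  subj <- cohort$subjects[[subject_id]]
  if (is.null(subj)) stop_arg("unknown subject_id: ", subject_id)
  subj$intervals
}
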