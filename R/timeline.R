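# Aggregation of per-epoch detections into per-interval totals and
# post-implant timelines.
#
# Automated durations are epoch-granular: every event-labeled 10 s epoch
# contributes its full 10 s, so an interval with ten flagged epochs logs
# 100 s of detected activity. Runs are maximal blocks of consecutive
# flagged epochs; an interval holding several separated runs is flagged as
# a cluster.

#' Aggregate one interval's predictions into a total duration and runs
#'
#' @param predictions data.frame from [classify_segments()] for a single
#'   interval (at most 180 rows, one per epoch).
#' @param epoch_s epoch length, seconds.
#' @param merge_gap_epochs merge runs separated by at most this many
#'   undetected epochs into one run (default 0 = off; 1 absorbs a single
#'   undetected mid-ictal-depression epoch).
#' @return list with `total_detected_s` (10 s per flagged epoch) and `runs`
#'   (data.frame `first_epoch`, `last_epoch`, `n_epochs`).
#' @export
aggregate_interval <- function(predictions, epoch_s = 10,
                               merge_gap_epochs = 0L) {
  if (anyDuplicated(predictions$epoch_index)) {
    stop_arg("duplicate epoch indices in interval predictions")
  }
  ev <- sort(predictions$epoch_index[predictions$label == "event"])
  total <- epoch_s * length(ev)
  if (length(ev) == 0) {
    runs <- data.frame(first_epoch = integer(0), last_epoch = integer(0),
                       n_epochs = integer(0))
  } else {
    brk <- which(diff(ev) > 1L + merge_gap_epochs)
    first <- ev[c(1L, brk + 1L)]
    last <- ev[c(brk, length(ev))]
    runs <- data.frame(first_epoch = first, last_epoch = last,
                       n_epochs = last - first + 1L)
  }
  list(total_detected_s = total, runs = runs)
}

#' Build a subject's post-implant detection timeline
#'
#' One entry per interval with at least one detection, sorted by
#' post-implant latency; intervals holding several separated detection runs
#' (possible seizure clusters) carry `n_runs >= 2`.
#'
#' @param predictions prediction data.frame for one subject (all intervals).
#' @param latency_map data.frame with `interval_index`, `latency_days` for
#'   every interval appearing in `predictions`.
#' @param event_kind label stored on the timeline (`"seizure"` or `"swd"`).
#' @param epoch_s epoch length, seconds.
#' @param merge_gap_epochs see [aggregate_interval()].
#' @return an object of class `detection_timeline`: data.frame with columns
#'   `subject_id`, `interval_index`, `latency_days`, `total_detected_s`,
#'   `n_runs`.
#' @export
build_timeline <- function(predictions, latency_map, event_kind = "seizure",
                           epoch_s = 10, merge_gap_epochs = 0L) {
  miss <- setdiff(unique(predictions$interval_index),
                  latency_map$interval_index)
  if (length(miss) > 0) {
    stop_arg("missing latency for interval(s): ", paste(miss, collapse = ", "))
  }
  entries <- list()
  for (ii in sort(unique(predictions$interval_index))) {
    pr <- predictions[predictions$interval_index == ii, , drop = FALSE]
    agg <- aggregate_interval(pr, epoch_s = epoch_s,
                              merge_gap_epochs = merge_gap_epochs)
    if (agg$total_detected_s > 0) {
      entries[[length(entries) + 1L]] <- data.frame(
        subject_id = pr$subject_id[1], interval_index = ii,
        latency_days = latency_map$latency_days[
          match(ii, latency_map$interval_index)],
        total_detected_s = agg$total_detected_s,
        n_runs = nrow(agg$runs), stringsAsFactors = FALSE)
    }
  }
  tl <- if (length(entries)) do.call(rbind, entries) else
    data.frame(subject_id = character(0), interval_index = integer(0),
               latency_days = numeric(0), total_detected_s = numeric(0),
               n_runs = integer(0), stringsAsFactors = FALSE)
  tl <- tl[order(tl$latency_days), , drop = FALSE]
  rownames(tl) <- NULL
  structure(tl, class = c("detection_timeline", "data.frame"),
            event_kind = event_kind)
}

#' Classify a post-implant latency as early or late
#'
#' Early means at most 5 days post-implant; later events define
#' post-traumatic epilepsy when they are seizures.
#'
#' @param latency_days non-negative latency in days (vectorized).
#' @return character vector `"early"` / `"late"`.
#' @export
classify_latency <- function(latency_days) {
  if (any(latency_days < 0)) stop_arg("latency must be >= 0")
  ifelse(latency_days <= 5, "early", "late")
}

#' Mean and SEM of per-interval detected durations
#'
#' Averages `total_detected_s` over intervals with detections (one or more
#' timelines row-bound). With a single entry the SEM is undefined and is
#' reported as 0 with `sem_defined = FALSE`.
#'
#' @param timeline a `detection_timeline` (or row-bound set of them).
#' @return list `mean_s`, `sem_s`, `n`, `sem_defined`.
#' @export
summarize_detection_durations <- function(timeline) {
  v <- timeline$total_detected_s
  if (length(v) == 0) stop_arg("no detection entries to summarize")
  n <- length(v)
  list(mean_s = mean(v),
       sem_s = if (n > 1) stats::sd(v) / sqrt(n) else 0,
       n = n, sem_defined = n > 1)
}

#' PTE status of a subject from its detection timeline
#'
#' A subject is classed as having post-traumatic epilepsy iff it shows at
#' least `threshold_late` detected late (> 5 d post-implant) event runs;
#' the default of 1 is the inclusive rule under which even a single
#' spontaneous late seizure confers PTE. Early runs alone never do.
#'
#' @param timeline a `detection_timeline` covering the subject's record.
#' @param threshold_late minimum number of late detection runs.
#' @return `"PTE"` or `"non-PTE"`.
#' @export
pte_status <- function(timeline, threshold_late = 1L) {
  late <- timeline$latency_days > 5
  n_late_runs <- sum(timeline$n_runs[late])
  if (n_late_runs >= threshold_late) "PTE" else "non-PTE"
}

#' Plot a detection timeline
#'
#' Vertical-line display: one line per interval with detections, placed at
#' its post-implant latency, height equal to the total detected seconds in
#' that 0.5 h interval; multi-run (cluster) intervals are marked.
#'
#' @param x a `detection_timeline`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.detection_timeline <- function(x, ...) {
  if (nrow(x) == 0) {
    graphics::plot(0, 0, type = "n", xlab = "Post-implant latency (d)",
                   ylab = "Detected activity (s / 0.5 h)", ...)
    return(invisible(x))
  }
  graphics::plot(x$latency_days, x$total_detected_s, type = "h",
                 xlab = "Post-implant latency (d)",
                 ylab = "Detected activity (s / 0.5 h)",
                 main = x$subject_id[1], ...)
  cl <- x$n_runs >= 2
  if (any(cl)) {
    graphics::points(x$latency_days[cl], x$total_detected_s[cl], pch = 15)
  }
  invisible(x)
}

#' Export a timeline to CSV
#' @param timeline a `detection_timeline`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(as.data.frame(timeline)[, c("subject_id", "interval_index",
                                               "latency_days",
                                               "total_detected_s", "n_runs")],
                   path, row.names = FALSE)
  invisible(path)
}
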