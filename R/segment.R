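# Epoch segmentation: contiguous 10 s windows, the unit the classifier sees.

#' Segment a record into contiguous 10 s epochs
#'
#' Slices a continuous record into non-overlapping, contiguous epochs of
#' `epoch_s` seconds (half-open on the right). A 0.5 h interval at 500 Hz
#' yields exactly 180 epochs. A trailing remainder shorter than one epoch is
#' dropped with a message; a record shorter than one epoch yields an empty
#' set with a warning.
#'
#' @param record an [eeg_record()].
#' @param epoch_s epoch length in seconds (default 10).
#' @param interval_index 0-based index of the parent 0.5 h interval, carried
#'   through to predictions.
#' @return an object of class `epoch_set`: a list with `samples` (matrix,
#'   one row per epoch), `fs`, `epoch_s`, `subject_id`, `interval_index`,
#'   `epoch_index` (0-based), `start_s`, and `t0_days`.
#' @export
segment_record <- function(record, epoch_s = 10, interval_index = 0L) {
  stopifnot(inherits(record, "eeg_record"))
  spe <- as.integer(round(epoch_s * record$fs))
  n <- length(record$samples)
  n_ep <- n %/% spe
  if (n_ep == 0L) {
    warning(sprintf("record %s is shorter than one %g s epoch; no epochs",
                    record$subject_id, epoch_s))
  } else if (n %% spe != 0L) {
    message(sprintf("segment_record: dropping trailing %.3f s of %s",
                    (n %% spe) / record$fs, record$subject_id))
  }
  samples <- if (n_ep > 0L) {
    matrix(record$samples[seq_len(n_ep * spe)], nrow = n_ep, byrow = TRUE)
  } else matrix(numeric(0), nrow = 0, ncol = spe)
  structure(list(samples = samples, fs = record$fs, epoch_s = epoch_s,
                 subject_id = record$subject_id,
                 interval_index = as.integer(interval_index),
                 epoch_index = seq_len(n_ep) - 1L,
                 start_s = (seq_len(n_ep) - 1L) * epoch_s,
                 t0_days = record$t0_days),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s interval %d: %d epochs of %g s @ %g Hz\n",
              x$subject_id, x$interval_index, nrow(x$samples), x$epoch_s, x$fs))
  invisible(x)
}

#' Number of epochs in a set
#' @param x an `epoch_set`.
#' @return integer count.
#' @export
n_epochs <- function(x) nrow(x$samples)
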