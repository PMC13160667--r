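# Minimal single-channel EDF (European Data Format) writer/reader.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by 16-bit
# little-endian samples in fixed-duration data records (1 s here). Voltages
# are linearly quantized between the physical min/max declared in the
# header, so a write/read round trip is exact to one quantization step.
# The post-implant latency is carried in the recording-id field.

edf_pad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write an EEG record to an EDF file
#'
#' One signal, 1 s data records, physical dimension uV, digital range
#' -32768..32767 spanning a symmetric physical range just above the trace
#' extremum. A trailing partial second is zero-padded.
#'
#' @param record an [eeg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- as.integer(round(record$fs))
  x <- record$samples
  ndr <- as.integer(ceiling(length(x) / fs))
  if (length(x) < ndr * fs) x <- c(x, numeric(ndr * fs - length(x)))
  # quantize with the exact affine map the header declares: physical range
  # [-pmax, pmax] at 2 decimals onto digital [-32768, 32767]
  pmax_ <- ceiling(max(abs(x), 1e-6) * 1.0001 * 100) / 100
  dig <- as.integer(round((x + pmax_) / (2 * pmax_) * 65535)) - 32768L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(record$subject_id, 80),
    edf_pad(sprintf("t0_days=%.8f", record$t0_days), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * 2L, 8),
    edf_pad("", 44),
    edf_pad(ndr, 8),
    edf_pad("1", 8),
    edf_pad("1", 4),
    # signal header
    edf_pad(record$channel, 16),
    edf_pad("synthetic EEG", 80),
    edf_pad("uV", 8),
    edf_pad(sprintf("%.2f", -pmax_), 8),
    edf_pad(sprintf("%.2f", pmax_), 8),
    edf_pad("-32768", 8), edf_pad("32767", 8),
    edf_pad("", 80),
    edf_pad(fs, 8),
    edf_pad("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' Counterpart of [write_edf()]; parses the header, rescales the 16-bit
#' samples to physical units, and recovers the post-implant latency if the
#' recording-id field carries one.
#'
#' @param path EDF file path.
#' @return an [eeg_record()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  subject <- trimws(rd(80))
  recid <- trimws(rd(80))
  rd(16)                                  # date + time
  rd(8)                                   # header bytes
  rd(44)
  ndr <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (ns != 1L) stop_arg("only single-signal EDF files are supported")
  label <- trimws(rd(16))
  rd(80)
  rd(8)                                   # physical dimension
  pmin_ <- as.numeric(trimws(rd(8)))
  pmax_ <- as.numeric(trimws(rd(8)))
  dmin <- as.numeric(trimws(rd(8)))
  dmax <- as.numeric(trimws(rd(8)))
  rd(80)
  spr <- as.integer(trimws(rd(8)))
  rd(32)
  dig <- readBin(con, "integer", n = ndr * spr, size = 2L, signed = TRUE,
                 endian = "little")
  x <- pmin_ + (dig - dmin) * (pmax_ - pmin_) / (dmax - dmin)
  t0 <- if (grepl("^t0_days=", recid)) {
    as.numeric(sub("^t0_days=", "", recid))
  } else 0
  eeg_record(x, fs = spr / dur, subject_id = subject, t0_days = t0,
             channel = label)
}

#' Write ground-truth annotations as CSV
#'
#' Standard annotation interchange: header
#' `subject_id,klass,phase,start_s,duration_s`, one row per event phase,
#' with `start_s` relative to the parent record.
#'
#' @param annotations annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(annotations[, c("subject_id", "klass", "phase",
                                   "start_s", "duration_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an annotations CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
read_annotations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the full annotation table as JSON (all fields)
#' @param annotations annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(annotations, path) {
  jsonlite::write_json(annotations, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Write a cohort to disk (EDF records + annotations + manifest)
#'
#' One EDF file and one annotation CSV per 0.5 h interval, per subject, plus
#' a cohort-wide JSON annotation mirror and a JSON manifest listing every
#' file. Rendering is streamed, one interval at a time.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created).
#' @return the manifest list, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (sid in names(cohort$subjects)) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    subj <- cohort$subjects[[sid]]
    for (ii in subj$intervals$interval_index) {
      rec <- render_interval(subj, ii)
      edf <- file.path(sdir, sprintf("interval_%03d.edf", ii))
      write_edf(rec, edf)
      ann <- subj$annotations[subj$annotations$interval_index == ii, ,
                              drop = FALSE]
      csv <- file.path(sdir, sprintf("interval_%03d.csv", ii))
      write_annotations_csv(ann, csv)
      files[[length(files) + 1L]] <- list(subject_id = sid,
                                          interval_index = ii,
                                          edf = edf, annotations = csv)
    }
  }
  write_annotations_json(cohort$annotations, file.path(dir, "annotations.json"))
  manifest <- cohort$manifest
  manifest$files <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(manifest)
}
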