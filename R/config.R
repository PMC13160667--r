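# Run configuration and YAML plumbing.

#' Pipeline run configuration
#'
#' Bundles the fixed pipeline parameters: sampling rate, 10 s epoching of
#' 0.5 h intervals, the 1-100 Hz scalogram band, the 0.99 detection
#' threshold, backbone width and image size. Validated invariants: the
#' epoch length divides the interval length, and the frequency band lies
#' within (0, fs/2\].
#'
#' @param fs sampling rate, Hz.
#' @param epoch_s epoch length, seconds.
#' @param interval_s stored-interval length, seconds.
#' @param freq_range scalogram band, Hz.
#' @param n_freqs scalogram frequency rows.
#' @param threshold detection confidence threshold.
#' @param channels conv-layer widths of the CNN backbone.
#' @param image_size rendered image side, pixels.
#' @param colormap scalogram colormap.
#' @param seed default master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(fs = 500, epoch_s = 10, interval_s = 1800,
                       freq_range = c(1, 100), n_freqs = 96,
                       threshold = 0.99, channels = c(8, 16, 32),
                       image_size = 64, colormap = "viridis", seed = 1) {
  if (interval_s %% epoch_s != 0) {
    stop_arg("`epoch_s` must divide `interval_s`")
  }
  if (freq_range[1] <= 0 || freq_range[2] > fs / 2) {
    stop_arg("`freq_range` must lie within (0, fs/2]")
  }
  if (threshold <= 0.5 || threshold >= 1) {
    stop_arg("`threshold` must be in (0.5, 1)")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys override [run_config()] defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(run_config)))
  do.call(run_config, lapply(vals[keep], unlist))
}

#' Read a cohort configuration from YAML
#'
#' Scalar fields map directly onto [cohort_config()] arguments; the nested
#' blocks `seizure_early`, `seizure_late` and `swd` override fields of
#' [seizure_params()] / [swd_params()].
#'
#' @param path YAML file.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  args <- list()
  for (nm in intersect(names(vals),
                       setdiff(names(formals(cohort_config)),
                               c("seizure_early", "seizure_late", "swd")))) {
    args[[nm]] <- unlist(vals[[nm]])
  }
  for (nm in c("seizure_early", "seizure_late")) {
    if (!is.null(vals[[nm]])) {
      args[[nm]] <- do.call(seizure_params, lapply(vals[[nm]], unlist))
    }
  }
  if (!is.null(vals$swd)) {
    args$swd <- do.call(swd_params, lapply(vals$swd, unlist))
  }
  do.call(cohort_config, args)
}

#' Write a run manifest (config hash, seed, versions) as JSON
#' @param path output JSON path.
#' @param seed seed used.
#' @param config_path configuration file hashed into the manifest (optional).
#' @param extra extra named fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, config_path = NULL, extra = list()) {
  manifest <- c(list(
    package = "scalodetect",
    version = as.character(utils::packageVersion("scalodetect")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA_character_),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load a trained detector
#'
#' The checkpoint is an RDS of the full detector; a JSON sidecar
#' (`<path>.json`) records backbone, threshold, seed, pool sizes and the
#' correction-loop iteration for provenance.
#'
#' @param model an `eeg_detector`.
#' @param path checkpoint path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "eeg_detector"))
  saveRDS(model, path)
  side <- list(event_kind = model$event_kind, threshold = model$threshold,
               channels = model$metadata$channels,
               seed = model$metadata$seed,
               val_accuracy = model$metadata$val_accuracy,
               n_event_pool = sum(model$pools$labels == "event"),
               n_background_pool = sum(model$pools$labels == "background"),
               correction_iteration = model$metadata$correction_iteration)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "eeg_detector"))
  model
}
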