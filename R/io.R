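## Plain-text artifact formats: recordings as a TSV sample matrix with a
## JSON sidecar (rate, labels, intervals), session logs as CSV, models
## as versioned JSON.

#' Write / read a recording pair
#'
#' The samples go to `<path>.tsv` (time-major, one column per channel)
#' and the metadata (sampling rate, channel labels, start time, class
#' intervals) to `<path>.json`.
#'
#' @param run list with `eeg`, optional `eog` and `labels` (as returned
#'   by [generate_run()]).
#' @param path base path without extension.
#' @return `read_recording()` returns the run list back.
#' @export
write_recording <- function(run, path) {
  utils::write.table(run$eeg$samples, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(run$eog))
    utils::write.table(run$eog$samples, paste0(path, "_eog.tsv"),
                       sep = "\t", row.names = FALSE, col.names = TRUE)
  meta <- list(fs = run$eeg$fs, channels = run$eeg$channels,
               start_time = run$eeg$start_time,
               labels = if (!is.null(run$labels))
                 as.data.frame(run$labels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t",
                                     header = TRUE, check.names = FALSE))
  out <- list(eeg = eeg_recording(eeg, meta$fs, meta$channels,
                                  meta$start_time %||% 0))
  eog_path <- paste0(path, "_eog.tsv")
  if (file.exists(eog_path))
    out$eog <- eog_recording(as.matrix(
      utils::read.table(eog_path, sep = "\t", header = TRUE)), meta$fs)
  if (!is.null(meta$labels) && length(meta$labels) > 0)
    out$labels <- run_labels(meta$labels$start, meta$labels$end,
                             meta$labels$class)
  out
}

#' Write / read a session log as CSV
#'
#' @param log a [session_log] data.frame.
#' @param path file path.
#' @return `read_session_log()` returns the validated [session_log].
#' @export
write_session_log <- function(log, path) {
  write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  as_session_log(read.csv(path, stringsAsFactors = FALSE))
}

#' Serialize / load a trained classifier as JSON
#'
#' @param model a [train_classifier()] model.
#' @param path file path.
#' @return `read_model()` returns the `bci_classifier`.
#' @export
write_model <- function(model, path) {
  obj <- list(format = "bciracer_model", version = 1,
              selected = model$selected,
              feature_names = model$feature_names,
              classes = model$classes,
              means = model$means, vars = model$vars,
              priors = model$priors,
              train_accuracy = model$train_accuracy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "bciracer_model"))
    stop("not a bciracer model file")
  structure(list(selected = obj$selected,
                 feature_names = obj$feature_names,
                 classes = obj$classes,
                 means = matrix(obj$means, nrow = length(obj$classes)),
                 vars = matrix(obj$vars, nrow = length(obj$classes)),
                 priors = obj$priors,
                 train_accuracy = obj$train_accuracy),
            class = "bci_classifier")
}
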