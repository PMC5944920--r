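#' EEG recording container
#'
#' A time-major multichannel EEG signal in microvolts with uniform
#' sampling.
#'
#' @param samples numeric matrix, time x channel.
#' @param fs sampling rate in Hz.
#' @param channels character vector of 10-20 labels, one per column.
#' @param start_time recording start in seconds.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channels, start_time = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) != length(channels))
    stop("channel count must equal label count")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (fs <= 0) stop("sampling rate must be positive")
  colnames(samples) <- channels
  structure(list(samples = samples, fs = fs, channels = channels,
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' EOG recording container
#'
#' Exactly four ocular sensors: EOG1 (right canthus), EOG2 (nasion),
#' EOG3 (left canthus), EOG4 (forehead, reference).
#'
#' @param samples numeric matrix, time x 4, microvolts.
#' @param fs sampling rate in Hz.
#' @param start_time recording start in seconds.
#' @return object of class `eog_recording`.
#' @export
eog_recording <- function(samples, fs, start_time = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 4) stop("EOG recording must have exactly 4 channels")
  colnames(samples) <- paste0("EOG", 1:4)
  structure(list(samples = samples, fs = fs,
                 channels = colnames(samples), start_time = start_time),
            class = "eog_recording")
}

#' @export
print.eog_recording <- function(x, ...) {
  cat(sprintf("<eog_recording> 4 channels x %.1f s @ %g Hz\n",
              nrow(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Class-label intervals for a run
#'
#' @param start,end interval bounds in seconds.
#' @param class character class per interval (e.g. `both_hands`,
#'   `both_feet`, `rest`).
#' @return data.frame of class `run_labels` with non-overlapping
#'   intervals.
#' @export
run_labels <- function(start, end, class) {
  d <- data.frame(start = as.numeric(start), end = as.numeric(end),
                  class = as.character(class), stringsAsFactors = FALSE)
  d <- d[order(d$start), , drop = FALSE]
  if (any(d$end <= d$start)) stop("intervals must have positive duration")
  if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)] - 1e-9))
    stop("intervals must not overlap")
  class(d) <- c("run_labels", "data.frame")
  d
}
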