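## Frame-wise EOG artifact detection and command gating. Derived
## channels follow the standard bipolar combinations: EOG_h = EOG1 -
## EOG3, EOG_v = EOG2 - (EOG1 + EOG3)/2, plus the average of the three
## active sensors, which is particularly sensitive to blinks and facial
## muscle flexions. Channels are band-pass filtered 1-10 Hz (2nd-order
## Butterworth, causal), rectified and compared frame-by-frame against a
## common threshold.

#' Artifact-detection configuration
#'
#' @param band band-pass edges, Hz.
#' @param order Butterworth filter order.
#' @param threshold_uv common amplitude threshold, microvolts.
#' @param frame_s frame length, seconds (the decoder's 62.5 ms grid).
#' @param timeout_s artifact offset is issued this long after the latest
#'   onset detection.
#' @return object of class `artifact_config`.
#' @export
artifact_config <- function(band = c(1, 10), order = 2,
                            threshold_uv = 25, frame_s = STEP_S,
                            timeout_s = 1.0) {
  if (threshold_uv <= 0) stop("threshold must be positive")
  if (timeout_s < frame_s) stop("timeout must be at least one frame")
  structure(list(band = band, order = order, threshold_uv = threshold_uv,
                 frame_s = frame_s, timeout_s = timeout_s),
            class = "artifact_config")
}

#' Derive the monitored EOG channels
#'
#' @param eog an [eog_recording()] (4 sensors).
#' @return object of class `eog_derived`: matrix with columns `EOG_h`,
#'   `EOG_v`, `EOG_avg` plus the sampling rate.
#' @export
derive_eog_channels <- function(eog) {
  if (!inherits(eog, "eog_recording") || ncol(eog$samples) != 4)
    stop("contract error: need a 4-channel EOG recording")
  x <- eog$samples
  d <- cbind(EOG_h = x[, 1] - x[, 3],
             EOG_v = x[, 2] - (x[, 1] + x[, 3]) / 2,
             EOG_avg = (x[, 1] + x[, 2] + x[, 3]) / 3)
  structure(list(samples = d, fs = eog$fs, start_time = eog$start_time),
            class = "eog_derived")
}

#' Frame-wise artifact decisions
#'
#' Filters and rectifies the derived channels, then decides each 62.5 ms
#' frame independently: the frame decision is 1 when any processed sample
#' of any channel within the frame exceeds the threshold, else 0.
#'
#' @param derived an [derive_eog_channels()] result.
#' @param cfg an [artifact_config()].
#' @return integer vector of per-frame 0/1 decisions; frame `k` covers
#'   `[(k - 1), k) * frame_s` (attribute `frame_s` records the grid).
#' @export
detect_frames <- function(derived, cfg = artifact_config()) {
  stopifnot(inherits(derived, "eog_derived"))
  fs <- derived$fs
  flen <- round(cfg$frame_s * fs)
  n <- nrow(derived$samples)
  if (n < flen) stop("signal shorter than one frame")
  bf <- signal::butter(cfg$order, cfg$band / (fs / 2), type = "pass")
  proc <- abs(apply(derived$samples, 2, function(ch)
    as.numeric(signal::filter(bf, ch))))
  nfr <- n %/% flen
  hit <- proc[seq_len(nfr * flen), , drop = FALSE] > cfg$threshold_uv
  frame_any <- colSums(matrix(rowSums(hit) > 0, nrow = flen)) > 0
  decisions <- as.integer(frame_any)
  attr(decisions, "frame_s") <- cfg$frame_s
  decisions
}

#' Turn frame decisions into onset/offset events
#'
#' An artifact onset is communicated at each 0-to-1 frame-decision
#' transition while the output is unblocked; the matching offset is
#' issued `timeout_s` after the latest onset detection, so later
#' transitions during a block extend it without emitting new events.
#'
#' @param decisions integer 0/1 vector from [detect_frames()].
#' @param cfg an [artifact_config()].
#' @return data.frame with `time` (s) and `kind` (`onset`/`offset`),
#'   strictly alternating.
#' @export
frames_to_events <- function(decisions, cfg = artifact_config()) {
  frame_s <- attr(decisions, "frame_s") %||% cfg$frame_s
  times <- (seq_along(decisions) - 1) * frame_s
  ev_t <- numeric(0); ev_k <- character(0)
  block_until <- -Inf
  prev <- 0L
  for (i in seq_along(decisions)) {
    d <- decisions[i]
    if (d == 1L && prev == 0L) {
      if (times[i] >= block_until) {      # new block
        if (is.finite(block_until)) {
          ev_t <- c(ev_t, block_until); ev_k <- c(ev_k, "offset")
        }
        ev_t <- c(ev_t, times[i]); ev_k <- c(ev_k, "onset")
      }
      block_until <- times[i] + cfg$timeout_s   # extend on every onset
    }
    prev <- d
  }
  if (is.finite(block_until)) {
    ev_t <- c(ev_t, block_until); ev_k <- c(ev_k, "offset")
  }
  data.frame(time = ev_t, kind = ev_k, stringsAsFactors = FALSE)
}

#' Gated intervals from an artifact event log
#'
#' @param events data.frame from [frames_to_events()].
#' @return 2-column matrix of `[onset, offset)` intervals, seconds.
#' @export
gated_intervals <- function(events) {
  on <- events$time[events$kind == "onset"]
  off <- events$time[events$kind == "offset"]
  if (length(on) != length(off)) stop("events must alternate onset/offset")
  cbind(onset = on, offset = off)
}

#' Full EOG-to-gate pipeline
#'
#' Convenience wrapper: derive channels, detect frames, build events and
#' return the gated intervals.
#'
#' @param eog an [eog_recording()].
#' @param cfg an [artifact_config()].
#' @return list with `events` and `intervals`.
#' @export
artifact_gate <- function(eog, cfg = artifact_config()) {
  ev <- frames_to_events(detect_frames(derive_eog_channels(eog), cfg), cfg)
  list(events = ev, intervals = gated_intervals(ev))
}
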