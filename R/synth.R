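## Synthetic EEG/EOG generation with a calibrated sensorimotor-rhythm
## (SMR) effect.
##
## The background on every channel is a 1/f^gamma Gaussian process with a
## white floor. On the designated effect channels the in-band component
## (default 22-32 Hz, i.e. the beta bins) is amplitude-modulated by the
## imagined class: both-feet imagery scales the band amplitude by
## rho^(1/4) (ERS-like), both-hands by rho^(-1/4) (ERD-like), rest is
## untouched, so the band-power ratio between the two motor-imagery
## classes is rho. The variance ratio is mapped in closed form to the
## Fisher score of log band power: for a chi-square-like Welch estimate
## whose log has variance V, FS = log(rho) / sqrt(2 V), hence
## rho = exp(effect_size * sqrt(2 V)).

## Marginal variance of the natural-log Welch band-power estimate for the
## pipeline's estimator (1 s window, 0.5 s Hann sub-segments, 50%
## overlap). Numerically validated: it equals trigamma(a_eff) with an
## effective chi-square shape a_eff ~ 2.89.
WELCH_LNPOWER_VAR <- 0.413

rho_from_effect_size <- function(effect_size) {
  exp(effect_size * sqrt(2 * WELCH_LNPOWER_VAR))
}

#' Synthetic-run configuration
#'
#' Describes a single synthetic recording: montage, trial schedule, the
#' channels and band carrying class-dependent SMR modulation, and the
#' dimensionless target separability (`effect_size`, the Fisher score the
#' log band-power feature converges to as the run grows).
#'
#' @param fs sampling rate, Hz.
#' @param channels ordered montage labels.
#' @param effect_channels channels carrying class-dependent modulation;
#'   the default is the whole 5 x 3 sensorimotor grid (both-hands vs
#'   both-feet imagery modulates the full strip), which also keeps the
#'   Fisher-score calibration exact after Laplacian filtering since every
#'   channel's in-band component scales identically.
#' @param effect_band numeric length 2, band bin labels in Hz; a bin
#'   labeled `f` covers `[f - 1, f + 1)` Hz, so the default `c(22, 32)`
#'   modulates 21-33 Hz.
#' @param effect_size target Fisher score per effect-channel band bin
#'   (0 = null effect). Must be >= 0.
#' @param trial_schedule data.frame with columns `class` and `duration`
#'   (seconds); see [alternating_schedule()].
#' @param noise list with `gamma` (spectral exponent), `rms` (background
#'   RMS amplitude, microvolts) and `white` (relative white floor).
#' @param eog_rms RMS amplitude of the quiescent EOG baseline, microvolts.
#' @param seed integer RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(fs = DEFAULT_FS,
                         channels = default_montage(),
                         effect_channels = setdiff(channels, "Fz"),
                         effect_band = c(22, 32),
                         effect_size = 1,
                         trial_schedule = alternating_schedule(),
                         noise = list(gamma = 1, rms = 20, white = 0.05),
                         eog_rms = 5,
                         seed = 1) {
  if (fs <= 0) stop("invalid config: sampling_rate must be positive")
  if (length(effect_band) != 2 || effect_band[1] > effect_band[2])
    stop("invalid config: effect_band must be an increasing pair")
  if (effect_band[1] - 1 < 0 || effect_band[2] + 1 >= fs / 2)
    stop("invalid config: effect_band outside (0, Nyquist)")
  if (effect_size < 0) stop("invalid config: effect_size must be >= 0")
  if (!all(effect_channels %in% channels))
    stop("invalid config: effect_channels must be montage members")
  trial_schedule <- as.data.frame(trial_schedule)
  if (!all(c("class", "duration") %in% names(trial_schedule)))
    stop("invalid config: trial_schedule needs class and duration columns")
  if (any(trial_schedule$duration <= 0))
    stop("invalid config: trial durations must be positive")
  noise <- modifyList(list(gamma = 1, rms = 20, white = 0.05), noise)
  structure(list(fs = fs, channels = channels,
                 effect_channels = effect_channels,
                 effect_band = as.numeric(effect_band),
                 effect_size = effect_size,
                 trial_schedule = trial_schedule,
                 noise = noise, eog_rms = eog_rms,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Alternating motor-imagery trial schedule
#'
#' @param trial_s duration of each trial, seconds.
#' @param n_trials total number of trials (alternating over `classes`).
#' @param classes classes to alternate.
#' @return data.frame with `class` and `duration` columns.
#' @export
alternating_schedule <- function(trial_s = 5, n_trials = 24,
                                 classes = c("both_hands", "both_feet")) {
  data.frame(class = rep(classes, length.out = n_trials),
             duration = rep(trial_s, n_trials), stringsAsFactors = FALSE)
}

## Amplitude spectral shape over the positive FFT bins of an n-sample
## record: sqrt(max(f, 1)^-gamma + white * max(1,1)^-gamma).
spectral_shape <- function(freqs, gamma, white) {
  sqrt(pmax(freqs, 1)^(-gamma) + white)
}

## Draw one colored-noise channel, optionally split into in-band and
## out-of-band parts (band in Hz over the fine FFT grid). Returns the
## series scaled so the full signal has expected per-sample variance
## rms^2, plus the expected in-band variance.
colored_noise_split <- function(n, fs, gamma, white, rms, band = NULL) {
  stopifnot(n %% 2 == 0)
  nf <- n / 2 - 1
  freqs <- (1:nf) * fs / n
  amp <- spectral_shape(freqs, gamma, white)
  nyq_amp <- spectral_shape(fs / 2, gamma, white)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  z_nyq <- rnorm(1) * nyq_amp
  S <- 4 * sum(amp^2) + nyq_amp^2
  scale <- rms * n / sqrt(S)
  build <- function(zi, nyq) {
    full <- complex(length.out = n)
    full[2:(nf + 1)] <- zi
    full[n / 2 + 1] <- nyq
    full[seq(n, n / 2 + 2)] <- Conj(zi)
    Re(fft(full, inverse = TRUE)) / n * scale
  }
  if (is.null(band)) {
    return(list(signal = build(z, z_nyq), band_var = NA_real_))
  }
  mask <- freqs >= band[1] & freqs < band[2]
  inb <- z; inb[!mask] <- 0
  outb <- z; outb[mask] <- 0
  band_var <- rms^2 * 4 * sum(amp[mask]^2) / S
  list(inband = build(inb, 0), outband = build(outb, z_nyq),
       band_var = band_var)
}

schedule_to_labels <- function(schedule) {
  ends <- cumsum(schedule$duration)
  run_labels(start = c(0, ends[-length(ends)]), end = ends,
             class = schedule$class)
}

## Per-sample band-amplitude gain from the label intervals.
class_gain_vector <- function(n, fs, labels, rho) {
  g <- rep(1, n)
  if (rho == 1) return(g)
  for (i in seq_len(nrow(labels))) {
    i0 <- floor(labels$start[i] * fs) + 1
    i1 <- min(n, ceiling(labels$end[i] * fs))
    if (i0 > n) next
    gain <- switch(labels$class[i],
                   both_feet  = rho^(1 / 4),
                   both_hands = rho^(-1 / 4),
                   1)
    g[i0:i1] <- gain
  }
  g
}

#' Generate one synthetic EEG + EOG run
#'
#' Produces background noise with the configured spectral shape on all
#' channels; on the effect channels the in-band component is scaled per
#' class so the empirical Fisher score of log band power converges to
#' `effect_size`. The paired EOG is quiescent low-amplitude noise (use
#' [inject_eog_artifacts()] to add ocular/muscle events). Identical
#' config and seed give bit-identical output.
#'
#' @param config a [synth_config()].
#' @return list with elements `eeg` ([eeg_recording()]), `eog`
#'   ([eog_recording()]) and `labels` ([run_labels()]).
#' @export
generate_run <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  labels <- schedule_to_labels(config$trial_schedule)
  total_s <- sum(config$trial_schedule$duration)
  n <- 2 * floor(total_s * config$fs / 2)
  rho <- rho_from_effect_size(config$effect_size)
  band_hz <- c(config$effect_band[1] - 1, config$effect_band[2] + 1)
  gain <- class_gain_vector(n, config$fs, labels, rho)
  with_seed(config$seed, {
    eeg <- matrix(0, n, length(config$channels))
    for (j in seq_along(config$channels)) {
      ch <- config$channels[j]
      if (ch %in% config$effect_channels) {
        parts <- colored_noise_split(n, config$fs, config$noise$gamma,
                                     config$noise$white, config$noise$rms,
                                     band = band_hz)
        eeg[, j] <- parts$outband + gain * parts$inband
      } else {
        eeg[, j] <- colored_noise_split(n, config$fs, config$noise$gamma,
                                        config$noise$white,
                                        config$noise$rms)$signal
      }
    }
    eog <- sapply(1:4, function(k)
      colored_noise_split(n, config$fs, 1.5, 0.05, config$eog_rms)$signal)
    list(eeg = eeg_recording(eeg, config$fs, config$channels),
         eog = eog_recording(eog, config$fs),
         labels = labels)
  })
}

derive_run_seed <- function(master_seed, run_index) {
  as.integer((as.numeric(master_seed) + 104729 * run_index) %% 2147483563)
}

#' Generate a multi-run training campaign
#'
#' One run per entry of `effect_schedule`, with per-run seeds derived
#' deterministically from `config$seed` and the run index. Emulates a
#' longitudinal training design in which the user's SMR separability
#' changes across runs.
#'
#' @param config base [synth_config()].
#' @param effect_schedule numeric vector of per-run effect sizes.
#' @return list of run lists as returned by [generate_run()].
#' @export
generate_campaign <- function(config, effect_schedule) {
  stopifnot(inherits(config, "synth_config"))
  if (length(effect_schedule) == 0) stop("invalid config: empty schedule")
  if (any(effect_schedule < 0))
    stop("invalid config: negative effect size")
  lapply(seq_along(effect_schedule), function(i) {
    cfg <- config
    cfg$effect_size <- effect_schedule[i]
    cfg$seed <- derive_run_seed(config$seed, i)
    generate_run(cfg)
  })
}

hann_pulse <- function(len) 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 0.5) / len)

#' Inject ocular/facial artifacts into an EOG recording
#'
#' Adds parametric transients: `blink` (vertical pulse on EOG2),
#' `saccade_h` (opposite-sign deflection on the two canthi, EOG1 vs
#' EOG3) and `muscle` (broadband burst on all sensors). Blink and
#' saccade templates concentrate their energy in 1-10 Hz.
#'
#' @param eog an [eog_recording()].
#' @param events data.frame with columns `time` (s), `kind`
#'   (`blink`, `saccade_h`, `muscle`) and `amplitude` (microvolts).
#' @return a new [eog_recording()] with the artifacts added.
#' @export
inject_eog_artifacts <- function(eog, events) {
  stopifnot(inherits(eog, "eog_recording"))
  events <- as.data.frame(events)
  if (nrow(events) == 0) return(eog)
  x <- eog$samples
  n <- nrow(x); fs <- eog$fs
  for (i in seq_len(nrow(events))) {
    t0 <- events$time[i]; kind <- as.character(events$kind[i])
    a <- events$amplitude[i]
    dur <- switch(kind, blink = 0.3, saccade_h = 0.3, muscle = 0.5,
                  stop("unknown artifact kind: ", kind))
    i0 <- floor(t0 * fs) + 1
    if (t0 < 0 || i0 > n) stop("artifact event outside recording span")
    len <- min(round(dur * fs), n - i0 + 1)
    idx <- i0:(i0 + len - 1)
    env <- hann_pulse(len)
    tt <- (seq_len(len) - 1) / fs
    if (kind == "blink") {
      x[idx, 2] <- x[idx, 2] + a * env
    } else if (kind == "saccade_h") {
      x[idx, 1] <- x[idx, 1] + a / 2 * env
      x[idx, 3] <- x[idx, 3] - a / 2 * env
    } else {
      burst <- env * (0.35 * sin(2 * pi * 6 * tt) +
                      0.65 * sin(2 * pi * 35 * tt))
      for (ch in 1:4)
        x[idx, ch] <- x[idx, ch] + a * burst * cos(ch)
    }
  }
  eog_recording(x, fs, eog$start_time)
}
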