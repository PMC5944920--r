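## End-to-end experiment orchestration: synthesize -> spatial filter ->
## band-power features -> feature selection -> classifier -> closed-loop
## race under a control paradigm -> evaluation metrics.
##
## Races are simulated truly closed-loop: at every 62.5 ms step the
## simulated pilot's intent is chosen from the pad the avatar currently
## occupies (matching motor imagery on action pads, rest on white pads,
## the alternating pair strategy on yellow pads under paradigm 4), one
## feature window of the corresponding intent stream is fed to the
## decoder, and any emitted command is applied to the race immediately.

## intent class needed to produce a given command under a 2-class map
class_for_command <- function(map, command) {
  cl <- names(map)[map == command]
  if (length(cl) == 0) NA_character_ else cl[1]
}

#' Simulate one closed-loop race
#'
#' @param track a [race_track()].
#' @param posteriors named list of posterior matrices (rows = windows,
#'   cols = classes), one per intent: the decision classes plus `rest`.
#' @param decoder a [decoder_config()].
#' @param paradigm a [paradigm_config()] (paradigms 2-4).
#' @param gate_intervals optional `[onset, offset)` matrix of artifact
#'   gated intervals.
#' @param max_s safety horizon, seconds.
#' @return list with the [simulate_race()]-style `result` and the
#'   decision log.
#' @export
closed_loop_race <- function(track, posteriors, decoder = decoder_config(),
                             paradigm = paradigm_config(4),
                             gate_intervals = NULL, max_s = 400) {
  stopifnot(inherits(track, "race_track"))
  map <- paradigm$map
  classes <- names(map)
  spin_class <- class_for_command(map, "spin")
  jump_class <- class_for_command(map, "jump")
  ptr <- setNames(rep(0L, length(posteriors)), names(posteriors))
  nrows <- vapply(posteriors, nrow, integer(1))
  s <- race_state_new(track)
  st <- integrator_state(length(classes))
  pst <- paradigm_state(paradigm, 0)
  dec_t <- numeric(0); dec_c <- character(0)
  cur_pad <- 1L
  yellow_target <- "spin"; slide_sent <- FALSE
  step <- decoder$step_s
  k <- 0L
  while (!s$finished) {
    k <- k + 1L
    t <- k * step
    if (t > max_s) break
    s <- race_advance(s, t)
    if (s$finished) break
    if (s$pad != cur_pad) {               # new pad: reset pilot strategy
      cur_pad <- s$pad
      yellow_target <- "spin"; slide_sent <- FALSE
    }
    type <- s$track$type[s$pad]
    intent <- switch(type,
      cyan = spin_class,
      magenta = jump_class,
      yellow = {
        if (paradigm$paradigm == 4 && !slide_sent) {
          if (yellow_target == "spin") spin_class else jump_class
        } else "rest"
      },
      "rest")
    ptr[intent] <- ptr[intent] %% nrows[intent] + 1L
    p <- posteriors[[intent]][ptr[intent], ]
    gated <- FALSE
    if (!is.null(gate_intervals) && nrow(gate_intervals) > 0)
      gated <- any(t >= gate_intervals[, 1] & t < gate_intervals[, 2])
    r <- step_integrator(st, p, decoder, t, gated)
    st <- r$state
    dcl <- if (is.null(r$decision)) NULL else classes[r$decision$class]
    if (is.null(dcl) && paradigm$paradigm != 3) next
    pr <- paradigm_step(pst, paradigm, t, dcl)
    pst <- pr$state
    if (!is.null(dcl)) {
      dec_t <- c(dec_t, t); dec_c <- c(dec_c, dcl)
      if (s$track$type[s$pad] == "yellow" && map[[dcl]] == yellow_target)
        yellow_target <- if (yellow_target == "spin") "jump" else "spin"
    }
    if (nrow(pr$commands) > 0) {
      for (i in seq_len(nrow(pr$commands))) {
        if (pr$commands$kind[i] == "slide" && s$track$type[s$pad] == "yellow")
          slide_sent <- TRUE
        s <- race_command(s, pr$commands$kind[i], pr$commands$time[i])
        if (s$finished) break
      }
    }
  }
  if (!s$finished) s <- race_advance(s, Inf)
  list(result = race_result_from_state(s),
       decisions = data.frame(time = dec_t, class = dec_c,
                              stringsAsFactors = FALSE))
}

#' Run a multi-run closed-loop training campaign
#'
#' For every run: generates a labeled calibration recording at the run's
#' programmed effect size, extracts Laplacian + Welch band-power
#' features, ranks features by discriminant power and trains the
#' Gaussian classifier; then generates per-intent feature streams, races
#' the standard track closed-loop under the configured paradigm, and
#' records race time, pad times, command accuracies and the four region
#' discriminancies. All randomness derives from `seed`.
#'
#' @param n_runs number of runs.
#' @param effect_schedule per-run SMR effect size (Fisher-score target);
#'   defaults to a linear ramp 0.1 to 1.
#' @param synth base [synth_config()] (montage, noise model).
#' @param decoder a [decoder_config()].
#' @param paradigm a [paradigm_config()]; the default pair timeout of
#'   6 s exceeds the refractory period plus the integrator's analytic
#'   time-to-decision at the default smoothing, so alternating pairs are
#'   feasible on yellow pads.
#' @param seed master seed.
#' @param calibration_s calibration-run length, seconds.
#' @param stream_s per-intent race stream length, seconds (windows are
#'   recycled if a race outlasts the stream).
#' @param n_features number of top-ranked features used by the
#'   classifier.
#' @param runs_per_session runs grouped into one session label.
#' @param verbose print one line per run.
#' @return a [session_log] data.frame.
#' @export
run_campaign <- function(n_runs = 20,
                         effect_schedule = seq(0.1, 1, length.out = n_runs),
                         synth = synth_config(),
                         decoder = decoder_config(),
                         paradigm = paradigm_config(4, pair_timeout_s = 6),
                         seed = 1,
                         calibration_s = 60,
                         stream_s = 60,
                         n_features = 24,
                         runs_per_session = 2,
                         verbose = FALSE) {
  stopifnot(length(effect_schedule) == n_runs, n_runs >= 1)
  if (any(effect_schedule < 0)) stop("invalid config: negative effect size")
  lap <- default_laplacian(synth$channels)
  classes <- names(paradigm$map)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    es <- effect_schedule[i]
    ## calibration run: alternating labeled trials
    cfg <- synth
    cfg$effect_size <- es
    cfg$trial_schedule <- alternating_schedule(
      trial_s = 5, n_trials = max(2, round(calibration_s / 5)),
      classes = classes)
    cfg$seed <- derive_run_seed(seed, i * 10 + 1)
    calib <- generate_run(cfg)
    feats <- welch_band_power(laplacian_filter(calib$eeg, lap),
                              labels = calib$labels)
    dmap <- discriminancy_map(feats, classes)
    ranked <- cva_rank_features(feats, classes)
    sel <- ranked$feature[seq_len(n_features)]
    model <- train_classifier(feats, sel, classes)
    sel_names <- colnames(feats$values)[sel]
    sel_chans <- unique(feats$features$channel[sel])
    stream_posteriors <- function(class, sub_seed) {
      scfg <- cfg
      scfg$trial_schedule <- data.frame(class = class,
                                        duration = stream_s)
      scfg$seed <- derive_run_seed(seed, sub_seed)
      run <- generate_run(scfg)
      f <- welch_band_power(laplacian_filter(run$eeg, lap),
                            channels = sel_chans)
      posterior_matrix(model, f$values[, sel_names])
    }
    posts <- list()
    for (j in seq_along(classes))
      posts[[classes[j]]] <- stream_posteriors(classes[j], i * 10 + 1 + j)
    posts[["rest"]] <- stream_posteriors("rest", i * 10 + 4)
    ## closed-loop race on a fresh track
    track <- generate_track(derive_run_seed(seed, i * 10 + 5))
    race <- closed_loop_race(track, posts, decoder, paradigm)
    acc <- command_accuracy(race$result)
    rows[[i]] <- data.frame(
      run = i,
      session = (i - 1) %/% runs_per_session + 1,
      race_time_s = race$result$completion_time,
      mean_pad_time_s = mean(race$result$pads$duration),
      accuracy = acc$overall,
      tnr_white = acc$tnr_white,
      disc_medial_beta = region_discriminancy(dmap, region_spec("medial", "beta")),
      disc_lateral_beta = region_discriminancy(dmap, region_spec("lateral", "beta")),
      disc_medial_mu = region_discriminancy(dmap, region_spec("medial", "mu")),
      disc_lateral_mu = region_discriminancy(dmap, region_spec("lateral", "mu")),
      paradigm = paradigm$paradigm)
    if (verbose)
      message(sprintf(
        "run %2d  effect %.2f  race %6.1f s  acc %5.1f%%  disc(beta,med) %.3f",
        i, es, rows[[i]]$race_time_s, rows[[i]]$accuracy,
        rows[[i]]$disc_medial_beta))
  }
  as_session_log(do.call(rbind, rows))
}
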