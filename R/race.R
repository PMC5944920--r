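## Deterministic pad-based race simulator. Mechanics are parameterized
## by time-to-cross per regime: each pad type defines the crossing time
## under the boost (correct command), base (no command) and penalty
## (erroneous command) regimes, and the avatar progresses piecewise at
## rate 1/t_regime pad-fractions per second. A correct command on an
## action pad switches to boost until the pad ends or a wrong command
## overrides it; any wrong command (including any command on a white
## pad) switches to penalty for 4 s, the timer being reset by further
## wrong commands and cut short by a correct command or the pad
## boundary. Regimes reset to base at every pad entry.

PENALTY_S <- 4

pad_regime_table <- function() {
  data.frame(
    type      = c("cyan", "magenta", "yellow", "white", "start_white",
                  "end_white"),
    command   = c("spin", "jump", "slide", NA, NA, NA),
    t_boost   = c(2, 2, 2, NA, NA, NA),
    t_base    = c(11, 11, 11, 5.5, 5, 3),
    t_penalty = c(19, 19, 19, 19, 13, 10),
    stringsAsFactors = FALSE)
}

#' Build a race track from a pad-type sequence
#'
#' @param types character vector of pad types among `cyan`, `magenta`,
#'   `yellow`, `white`, `start_white`, `end_white`.
#' @return object of class `race_track`: a data.frame with per-pad
#'   regime crossing times.
#' @export
race_track <- function(types) {
  tab <- pad_regime_table()
  i <- match(types, tab$type)
  if (anyNA(i)) stop("unknown pad type: ",
                     paste(types[is.na(i)], collapse = ", "))
  d <- tab[i, , drop = FALSE]
  d$pad <- seq_along(types)
  rownames(d) <- NULL
  structure(d[, c("pad", "type", "command", "t_boost", "t_base",
                  "t_penalty")],
            class = c("race_track", "data.frame"))
}

#' Generate the standard 18-pad track
#'
#' A starting white pad, sixteen pads (four each of cyan, magenta,
#' yellow and white) in a seed-reproducible random order, and an ending
#' white pad.
#'
#' @param seed integer seed controlling the pad permutation.
#' @return a [race_track()].
#' @export
generate_track <- function(seed = 1) {
  middle <- with_seed(seed,
    sample(rep(c("cyan", "magenta", "yellow", "white"), 4)))
  track <- race_track(c("start_white", middle, "end_white"))
  attr(track, "seed") <- seed
  track
}

#' @export
print.race_track <- function(x, ...) {
  cat(sprintf("<race_track> %d pads: %s\n", nrow(x),
              paste(substr(x$type, 1, 2), collapse = " ")))
  invisible(x)
}

## --- incremental race state machine -------------------------------------

race_state_new <- function(track) {
  list(track = track, t = 0, pad = 1L, frac = 0, regime = "base",
       penalty_until = -Inf, finished = FALSE,
       entry = c(0, rep(NA_real_, nrow(track) - 1)),
       exit = rep(NA_real_, nrow(track)),
       cmd_pad = integer(0), cmd_time = numeric(0),
       cmd_kind = character(0), cmd_correct = logical(0))
}

regime_time <- function(track, pad, regime) {
  switch(regime,
         boost = track$t_boost[pad],
         base = track$t_base[pad],
         penalty = track$t_penalty[pad])
}

## advance the avatar to absolute time t_target (or the finish line)
race_advance <- function(s, t_target) {
  while (!s$finished && s$t < t_target - 1e-12) {
    tr <- regime_time(s$track, s$pad, s$regime)
    t_pad_end <- s$t + (1 - s$frac) * tr
    t_next <- min(t_target, t_pad_end)
    if (s$regime == "penalty" && s$penalty_until < t_next - 1e-12) {
      s$frac <- s$frac + (s$penalty_until - s$t) / tr
      s$t <- s$penalty_until
      s$regime <- "base"
      next
    }
    if (t_pad_end <= t_target + 1e-12) {   # pad boundary reached
      s$exit[s$pad] <- t_pad_end
      s$t <- t_pad_end
      if (s$pad == nrow(s$track)) {
        s$finished <- TRUE
        s$frac <- 0
      } else {
        s$pad <- s$pad + 1L
        s$frac <- 0
        s$regime <- "base"                 # regimes reset at pad entry
        s$penalty_until <- -Inf
        s$entry[s$pad] <- t_pad_end
      }
    } else {
      s$frac <- s$frac + (t_next - s$t) / tr
      s$t <- t_next
    }
  }
  s
}

## deliver one command at absolute time t
race_command <- function(s, kind, t) {
  s <- race_advance(s, t)
  if (s$finished) return(s)
  correct <- !is.na(s$track$command[s$pad]) &&
    kind == s$track$command[s$pad]
  s$cmd_pad <- c(s$cmd_pad, s$pad)
  s$cmd_time <- c(s$cmd_time, t)
  s$cmd_kind <- c(s$cmd_kind, kind)
  s$cmd_correct <- c(s$cmd_correct, correct)
  if (correct) {
    s$regime <- "boost"                    # overrides any penalty
    s$penalty_until <- -Inf
  } else {
    s$regime <- "penalty"
    s$penalty_until <- t + PENALTY_S       # reset by every wrong command
  }
  s
}

race_result_from_state <- function(s) {
  track <- s$track
  pads <- data.frame(
    pad = track$pad, type = track$type,
    entry = s$entry, exit = s$exit,
    duration = s$exit - s$entry, stringsAsFactors = FALSE)
  pads$n_commands <- vapply(track$pad, function(p)
    sum(s$cmd_pad == p), integer(1))
  pads$correct_delivered <- vapply(track$pad, function(p)
    any(s$cmd_pad == p & s$cmd_correct), logical(1))
  commands <- data.frame(time = s$cmd_time, kind = s$cmd_kind,
                         pad = s$cmd_pad, correct = s$cmd_correct,
                         stringsAsFactors = FALSE)
  structure(list(completion_time = s$t, pads = pads, commands = commands,
                 valid = s$t < 240),
            class = "race_result")
}

#' Simulate a race
#'
#' Runs the avatar over the track under a time-ordered command stream
#' and returns the completion time with a full per-pad audit.
#'
#' @param track a [race_track()] or [generate_track()].
#' @param commands data.frame with `time` (s) and `kind`
#'   (`spin`/`jump`/`slide`); may be empty.
#' @return object of class `race_result` with `completion_time`, per-pad
#'   records (`pads`), the attributed `commands` and the `valid` flag
#'   (completion below the 240 s competition cap).
#' @export
simulate_race <- function(track, commands = NULL) {
  stopifnot(inherits(track, "race_track"))
  s <- race_state_new(track)
  if (!is.null(commands) && nrow(commands) > 0) {
    if (is.unsorted(commands$time)) stop("commands must be time-ordered")
    if (any(commands$time < 0)) {
      warning("commands before race start ignored")
      commands <- commands[commands$time >= 0, , drop = FALSE]
    }
    for (i in seq_len(nrow(commands)))
      s <- race_command(s, commands$kind[i], commands$time[i])
  }
  s <- race_advance(s, Inf)
  race_result_from_state(s)
}

#' @export
print.race_result <- function(x, ...) {
  cat(sprintf("<race_result> completed in %.2f s (%svalid), %d commands\n",
              x$completion_time, if (x$valid) "" else "in",
              nrow(x$commands)))
  invisible(x)
}

#' Per-pad crossing times
#'
#' @param result a [simulate_race()] result.
#' @param by_type if `TRUE`, also return mean duration per pad type.
#' @return data.frame of per-pad durations (and optionally a `by_type`
#'   attribute); their sum equals the completion time.
#' @export
pad_crossing_times <- function(result, by_type = TRUE) {
  stopifnot(inherits(result, "race_result"))
  d <- result$pads[, c("pad", "type", "duration")]
  if (by_type)
    attr(d, "by_type") <- tapply(d$duration, d$type, mean)
  d
}

## --- canonical command streams -------------------------------------------

#' Ideal, empty and adversarial command streams for a track
#'
#' `ideal_commands()` delivers the correct command at each action-pad
#' entry and stays silent on white pads; `adversarial_commands()`
#' delivers a wrong command at every pad entry, renewed before each 4 s
#' penalty expires, keeping every pad in the penalty regime for its
#' whole crossing.
#'
#' @param track a [race_track()].
#' @return data.frame of commands (`time`, `kind`).
#' @export
ideal_commands <- function(track) {
  stopifnot(inherits(track, "race_track"))
  dur <- ifelse(is.na(track$t_boost), track$t_base, track$t_boost)
  entries <- cumsum(c(0, dur[-nrow(track)]))
  act <- !is.na(track$command)
  data.frame(time = entries[act], kind = track$command[act],
             stringsAsFactors = FALSE)
}

#' @rdname ideal_commands
#' @param renew_s interval between renewed wrong commands (must stay
#'   below the 4 s penalty timer).
#' @export
adversarial_commands <- function(track, renew_s = 3) {
  stopifnot(inherits(track, "race_track"), renew_s < PENALTY_S)
  entries <- cumsum(c(0, track$t_penalty[-nrow(track)]))
  exits <- entries + track$t_penalty
  wrong <- ifelse(is.na(track$command) | track$command != "spin",
                  "spin", "jump")
  out <- lapply(seq_len(nrow(track)), function(p) {
    t <- seq(entries[p], exits[p] - 1e-9, by = renew_s)
    data.frame(time = t, kind = wrong[p], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Analytic race-bound table recomputed by simulation
#'
#' Runs the simulator with ideal, empty and adversarial streams on a
#' standard track and on single pads of every type, returning the
#' resulting crossing-time bounds (a self-test of the mechanics).
#'
#' @param seed track seed for the standard-track rows.
#' @return data.frame with one row per (scope, regime) bound.
#' @export
race_bounds <- function(seed = 1) {
  track <- generate_track(seed)
  rows <- list(
    data.frame(scope = "track", regime = "ideal",
               time_s = simulate_race(track, ideal_commands(track))$completion_time),
    data.frame(scope = "track", regime = "no_input",
               time_s = simulate_race(track)$completion_time),
    data.frame(scope = "track", regime = "penalty",
               time_s = simulate_race(track, adversarial_commands(track))$completion_time))
  for (tp in pad_regime_table()$type) {
    tr1 <- race_track(tp)
    if (!is.na(tr1$command[1]))
      rows[[length(rows) + 1]] <- data.frame(
        scope = tp, regime = "boost",
        time_s = simulate_race(tr1, data.frame(time = 0,
          kind = tr1$command[1]))$completion_time)
    rows[[length(rows) + 1]] <- data.frame(
      scope = tp, regime = "no_input",
      time_s = simulate_race(tr1)$completion_time)
    rows[[length(rows) + 1]] <- data.frame(
      scope = tp, regime = "penalty",
      time_s = simulate_race(tr1, adversarial_commands(tr1))$completion_time)
  }
  do.call(rbind, rows)
}
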