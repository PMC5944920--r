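## Game-control paradigms: how emitted BCI decisions translate into
## avatar commands (spin, jump, slide).
##
## Paradigm 1: 3-class BCI, one decision class per command.
## Paradigm 2: 2-class BCI mapped to spin/jump; slide unsupported.
## Paradigm 3: 2-class mapped to spin/jump; a slide is triggered after a
##   configurable period of intentional non-control (re-armed after every
##   decision or emitted slide).
## Paradigm 4: 2-class mapped to spin/jump, forwarded as they occur; two
##   consecutive decisions of different types within a configurable
##   interval additionally trigger a slide at the second decision.

EMPTY_COMMANDS <- data.frame(time = numeric(0), kind = character(0),
                             stringsAsFactors = FALSE)

#' Paradigm configuration
#'
#' @param paradigm integer 1-4.
#' @param map named character vector decision class -> command. Paradigm
#'   1 needs three classes covering spin/jump/slide; paradigms 2-4 need
#'   two classes covering spin and jump.
#' @param inactivity_s paradigm-3 idle period before a slide, seconds.
#' @param pair_timeout_s paradigm-4 maximum interval between the two
#'   decisions of a slide-triggering pair, seconds.
#' @return object of class `paradigm_config`.
#' @export
paradigm_config <- function(paradigm = 4,
                            map = NULL,
                            inactivity_s = 3,
                            pair_timeout_s = 2) {
  if (!paradigm %in% 1:4) stop("config error: paradigm must be 1-4")
  if (is.null(map)) {
    map <- if (paradigm == 1)
      c(right_hand = "spin", both_feet = "jump", left_hand = "slide")
    else c(both_hands = "spin", both_feet = "jump")
  }
  need <- if (paradigm == 1) 3L else 2L
  if (length(map) != need)
    stop("config error: paradigm ", paradigm, " requires ", need,
         " classes")
  structure(list(paradigm = as.integer(paradigm), map = map,
                 inactivity_s = inactivity_s,
                 pair_timeout_s = pair_timeout_s),
            class = "paradigm_config")
}

#' Fresh online paradigm state
#'
#' @param cfg a [paradigm_config()].
#' @param t0 stream start time, seconds.
#' @return opaque state list for [paradigm_step()].
#' @export
paradigm_state <- function(cfg, t0 = 0) {
  list(armed_class = NA_character_, armed_time = -Inf,
       next_slide_due = t0 + cfg$inactivity_s)
}

#' One online paradigm step
#'
#' Advances the paradigm clock to `t` and optionally consumes one
#' decision arriving at `t`. Paradigm-3 idle slides due strictly before
#' or at `t` (and before the decision) are emitted here.
#'
#' @param state a [paradigm_state()].
#' @param cfg a [paradigm_config()].
#' @param t current time, seconds.
#' @param decision_class decision class label arriving at `t`, or `NULL`.
#' @return list with the updated `state` and `commands` (data.frame
#'   `time`, `kind`).
#' @export
paradigm_step <- function(state, cfg, t, decision_class = NULL) {
  cmd_t <- numeric(0); cmd_k <- character(0)
  if (cfg$paradigm == 3) {
    while (state$next_slide_due <= t + 1e-9 &&
           (is.null(decision_class) ||
            state$next_slide_due < t - 1e-9)) {
      cmd_t <- c(cmd_t, state$next_slide_due)
      cmd_k <- c(cmd_k, "slide")
      state$next_slide_due <- state$next_slide_due + cfg$inactivity_s
    }
  }
  if (!is.null(decision_class)) {
    if (!decision_class %in% names(cfg$map))
      stop("config error: decision class '", decision_class,
           "' not in paradigm map")
    kind <- unname(cfg$map[[decision_class]])
    cmd_t <- c(cmd_t, t); cmd_k <- c(cmd_k, kind)
    if (cfg$paradigm == 4) {
      if (!is.na(state$armed_class) && state$armed_class != kind &&
          t - state$armed_time <= cfg$pair_timeout_s + 1e-9) {
        cmd_t <- c(cmd_t, t); cmd_k <- c(cmd_k, "slide")
        state$armed_class <- NA_character_   # pair window resets
      } else {
        state$armed_class <- kind; state$armed_time <- t
      }
    }
    state$next_slide_due <- t + cfg$inactivity_s
  }
  cmds <- if (length(cmd_t) == 0) EMPTY_COMMANDS
          else data.frame(time = cmd_t, kind = cmd_k,
                          stringsAsFactors = FALSE)
  list(state = state, commands = cmds)
}

#' Map a decision stream to game commands
#'
#' @param decisions data.frame with `time` and `class` (as returned by
#'   [run_decoder()]), ordered in time.
#' @param cfg a [paradigm_config()].
#' @param t_start,t_end stream span, seconds (`t_end` defaults to the
#'   last decision time; paradigm 3 emits idle slides up to `t_end`).
#' @return data.frame of commands: `time`, `kind`.
#' @export
map_decisions <- function(decisions, cfg, t_start = 0, t_end = NULL) {
  stopifnot(inherits(cfg, "paradigm_config"))
  if (is.null(t_end))
    t_end <- if (nrow(decisions) > 0) max(decisions$time) else t_start
  st <- paradigm_state(cfg, t_start)
  out <- list()
  for (i in seq_len(nrow(decisions))) {
    r <- paradigm_step(st, cfg, decisions$time[i], decisions$class[i])
    st <- r$state
    out[[length(out) + 1]] <- r$commands
  }
  r <- paradigm_step(st, cfg, t_end, NULL)
  out[[length(out) + 1]] <- r$commands
  cmds <- do.call(rbind, out)
  cmds[order(cmds$time), , drop = FALSE]
}

#' Intentional non-control (idle) indicator per window
#'
#' `TRUE` for half-open windows `[t, t + window_s)` containing no
#' decision; a decision exactly on a boundary belongs to the later
#' window.
#'
#' @param decisions data.frame with a `time` column.
#' @param window_s window length, seconds.
#' @param t_start,t_end span to cover; windows are
#'   `t_start + (k - 1) * window_s`, `k = 1..floor((t_end - t_start) /
#'   window_s)`.
#' @return logical vector, one element per window.
#' @export
inc_idle <- function(decisions, window_s, t_start = 0,
                     t_end = NULL) {
  if (is.null(t_end))
    t_end <- if (nrow(decisions) > 0) max(decisions$time) + window_s
             else t_start + window_s
  nw <- floor((t_end - t_start) / window_s)
  if (nw < 1) return(logical(0))
  starts <- t_start + (seq_len(nw) - 1) * window_s
  vapply(starts, function(s)
    !any(decisions$time >= s & decisions$time < s + window_s),
    logical(1))
}
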