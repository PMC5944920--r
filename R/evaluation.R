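## Performance and learning metrics: per-command accuracies on a race,
## Pearson trend tests over a training campaign, and first-vs-last-k
## session rank-sum contrasts.

#' Command accuracy of one race
#'
#' A colored pad counts as correct when its matching command was
#' delivered while the avatar was on it; a white pad counts as a true
#' negative when it was crossed without any command. The overall
#' accuracy is the arithmetic mean of the three per-command
#' true-positive rates (the white-pad true-negative rate is reported
#' separately and excluded from the mean). Rates for absent pad types
#' are `NA` and excluded.
#'
#' @param result a [simulate_race()] result.
#' @return object of class `accuracy_report`: per-command rates (%),
#'   `overall` (%), `tnr_white` (%), and pad counts.
#' @export
command_accuracy <- function(result) {
  stopifnot(inherits(result, "race_result"))
  pads <- result$pads
  rate <- function(type) {
    sel <- pads$type == type
    if (!any(sel)) return(NA_real_)
    100 * mean(pads$correct_delivered[sel])
  }
  per <- c(spin = rate("cyan"), jump = rate("magenta"),
           slide = rate("yellow"))
  white <- pads$type %in% c("white", "start_white", "end_white")
  tnr <- if (any(white)) 100 * mean(pads$n_commands[white] == 0)
         else NA_real_
  counts <- table(factor(pads$type, levels = pad_regime_table()$type))
  structure(list(per_command = per,
                 overall = mean(per, na.rm = TRUE),
                 tnr_white = tnr,
                 n_pads = counts),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> overall %.1f%% (spin %.0f, jump %.0f, slide %.0f), white TNR %.1f%%\n",
    x$overall, x$per_command["spin"], x$per_command["jump"],
    x$per_command["slide"], x$tnr_white))
  invisible(x)
}

#' Pearson trend test
#'
#' Pearson correlation of an ordered metric series against run index,
#' with a two-sided p-value from the Student-t transform on n - 2
#' degrees of freedom.
#'
#' @param values numeric metric series.
#' @param index run indices (defaults to `seq_along(values)`).
#' @return list with `r`, `p` and `n`. Zero variance in either series
#'   gives `r = NA` with a warning.
#' @export
trend_correlation <- function(values, index = seq_along(values)) {
  keep <- is.finite(values) & is.finite(index)
  values <- values[keep]; index <- index[keep]
  if (length(values) < 3) stop("need at least 3 points")
  if (sd(values) == 0 || sd(index) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(values)))
  }
  ct <- cor.test(index, values, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values))
}

#' First-vs-last sessions rank-sum contrast
#'
#' Pools all runs of the first `k` and of the last `k` sessions of a
#' campaign log and compares a metric between the two pools with an
#' unpaired two-sided Wilcoxon rank-sum test (exact for small untied
#' samples, normal approximation with tie correction otherwise).
#'
#' @param log a [session_log] data.frame.
#' @param metric column name of the metric to contrast.
#' @param k_sessions number of sessions in each window.
#' @return list with the group medians/means, sizes, `p` and the `W`
#'   statistic.
#' @export
first_last_contrast <- function(log, metric, k_sessions = 4) {
  sessions <- unique(log$session)
  if (length(sessions) < 2 * k_sessions)
    stop("contract error: need at least ", 2 * k_sessions, " sessions")
  first <- log[[metric]][log$session %in% utils::head(sessions, k_sessions)]
  last <- log[[metric]][log$session %in% utils::tail(sessions, k_sessions)]
  wt <- suppressWarnings(wilcox.test(first, last, exact = NULL,
                                     correct = TRUE))
  list(first_median = median(first), last_median = median(last),
       first_mean = mean(first), last_mean = mean(last),
       n = c(length(first), length(last)),
       W = unname(wt$statistic), p = wt$p.value)
}

#' Campaign session log
#'
#' One row per run: `run`, `session`, `race_time_s`, `mean_pad_time_s`,
#' `accuracy`, `tnr_white`, the four region discriminancies
#' (`disc_medial_beta`, `disc_lateral_beta`, `disc_medial_mu`,
#' `disc_lateral_mu`) and `paradigm`. Built by [run_campaign()] or read
#' from CSV with [read_session_log()].
#'
#' @name session_log
NULL

session_log_columns <- c("run", "session", "race_time_s",
                         "mean_pad_time_s", "accuracy", "tnr_white",
                         "disc_medial_beta", "disc_lateral_beta",
                         "disc_medial_mu", "disc_lateral_mu", "paradigm")

as_session_log <- function(d) {
  missing <- setdiff(session_log_columns, names(d))
  if (length(missing) > 0)
    stop("session log missing columns: ", paste(missing, collapse = ", "))
  if (is.unsorted(d$run, strictly = TRUE))
    stop("run indices must be strictly increasing")
  class(d) <- c("session_log", "data.frame")
  d
}

#' Longitudinal learning report
#'
#' Computes the full battery of campaign statistics: Pearson trends of
#' race completion time, mean pad crossing time, command accuracy and
#' medial-beta discriminancy against run index; the cross-correlations
#' of discriminancy with accuracy, pad time and race time; first-vs-last
#' `k`-session rank-sum contrasts per metric; and per-paradigm
#' aggregates.
#'
#' @param log a [session_log] data.frame.
#' @param k_sessions window for the first/last contrast (skipped, with a
#'   message in the report, when the log has too few sessions).
#' @param disc_metric discriminancy column used for cross-correlations.
#' @return object of class `learning_report`.
#' @export
learning_report <- function(log, k_sessions = 4,
                            disc_metric = "disc_medial_beta") {
  log <- as_session_log(as.data.frame(log))
  tr <- list(
    race_time_vs_run = trend_correlation(log$race_time_s, log$run),
    pad_time_vs_run = trend_correlation(log$mean_pad_time_s, log$run),
    accuracy_vs_run = trend_correlation(log$accuracy, log$run),
    discriminancy_vs_run = trend_correlation(log[[disc_metric]], log$run),
    discriminancy_vs_accuracy =
      list_cor(log[[disc_metric]], log$accuracy),
    discriminancy_vs_pad_time =
      list_cor(log[[disc_metric]], log$mean_pad_time_s),
    discriminancy_vs_race_time =
      list_cor(log[[disc_metric]], log$race_time_s))
  contrasts <- NULL
  if (length(unique(log$session)) >= 2 * k_sessions) {
    metrics <- c("race_time_s", "mean_pad_time_s", "accuracy",
                 disc_metric)
    contrasts <- lapply(setNames(metrics, metrics), function(m)
      first_last_contrast(log, m, k_sessions))
  }
  by_paradigm <- do.call(rbind, lapply(split(log, log$paradigm),
    function(d) data.frame(paradigm = d$paradigm[1], n_runs = nrow(d),
                           mean_race_time_s = mean(d$race_time_s),
                           mean_accuracy = mean(d$accuracy),
                           mean_tnr_white = mean(d$tnr_white))))
  structure(list(trends = tr, contrasts = contrasts,
                 by_paradigm = by_paradigm, n_runs = nrow(log)),
            class = "learning_report")
}

## Pearson correlation between two metric series (same t-transform)
list_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' @export
print.learning_report <- function(x, ...) {
  cat(sprintf("<learning_report> %d runs\n", x$n_runs))
  for (nm in names(x$trends)) {
    t <- x$trends[[nm]]
    cat(sprintf("  %-28s r = %+.3f  p = %.4g\n", nm, t$r, t$p))
  }
  if (!is.null(x$contrasts)) {
    cat("  first/last session contrasts:\n")
    for (nm in names(x$contrasts)) {
      ct <- x$contrasts[[nm]]
      cat(sprintf("    %-18s %.2f -> %.2f (p = %.4g)\n", nm,
                  ct$first_median, ct$last_median, ct$p))
    }
  }
  invisible(x)
}
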