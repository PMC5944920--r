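## Online probabilistic decoder: diagonal Gaussian classifier over
## selected spatiospectral features, sample rejection, leaky-integrator
## evidence accumulation, thresholded command emission with reset and a
## refractory period.

#' Decoder configuration
#'
#' @param rejection rejection threshold rho in `[0, 1]`: posteriors whose
#'   maximum does not exceed it are discarded before accumulation.
#' @param alpha leaky-integrator retention per 62.5 ms step, in `[0, 1)`.
#' @param thresholds per-class decision thresholds in `(1/n_classes, 1]`
#'   (recycled to the number of classes at run time).
#' @param refractory_s minimum interval between consecutive emitted
#'   decisions, seconds.
#' @param step_s decoder step, seconds.
#' @param refractory_mode `"reset"`: evidence keeps integrating during the
#'   refractory period but emission is suppressed and the integrator is
#'   re-reset to uniform when it ends; `"freeze"`: the state is frozen
#'   until the refractory period elapses.
#' @return object of class `decoder_config`.
#' @export
decoder_config <- function(rejection = 0.55, alpha = 0.96,
                           thresholds = 0.9, refractory_s = 1.0,
                           step_s = STEP_S,
                           refractory_mode = c("reset", "freeze")) {
  if (rejection < 0 || rejection > 1) stop("rejection must be in [0, 1]")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (any(thresholds <= 0.5) || any(thresholds > 1))
    stop("decision thresholds must be in (0.5, 1]")
  if (rejection >= max(thresholds))
    warning("rejection threshold at or above the decision threshold: ",
            "every sample will be rejected and no decision can be emitted")
  structure(list(rejection = rejection, alpha = alpha,
                 thresholds = thresholds, refractory_s = refractory_s,
                 step_s = step_s,
                 refractory_mode = match.arg(refractory_mode)),
            class = "decoder_config")
}

#' Train the Gaussian classifier
#'
#' One Gaussian prototype per class with diagonal covariance and uniform
#' priors, fit by closed-form moment estimates on the selected features;
#' optionally refined by gradient descent on the cross-entropy of the
#' posteriors (`method = "gradient"`).
#'
#' @param features a labeled [feature_matrix].
#' @param selected integer vector of feature columns to use (e.g. the
#'   head of [cva_rank_features()]).
#' @param classes the two (or more) class names.
#' @param method `"closed_form"` or `"gradient"`.
#' @param gd_iter,gd_lr gradient-refinement iterations and learning rate.
#' @return object of class `bci_classifier` with per-class `means`,
#'   `vars`, `priors` and the training accuracy.
#' @export
train_classifier <- function(features, selected,
                             classes = c("both_hands", "both_feet"),
                             method = c("closed_form", "gradient"),
                             gd_iter = 50, gd_lr = 0.05) {
  stopifnot(inherits(features, "feature_matrix"))
  method <- match.arg(method)
  rows <- lapply(classes, function(cl) which(features$labels %in% cl))
  if (any(lengths(rows) < 2))
    stop("training error: every class needs at least 2 windows")
  x <- features$values[, selected, drop = FALSE]
  means <- t(sapply(rows, function(i) colMeans(x[i, , drop = FALSE])))
  vars <- t(sapply(rows, function(i) {
    v <- apply(x[i, , drop = FALSE], 2, var)
    v
  }))
  floor_v <- 1e-6 * mean(apply(x, 2, var))
  if (any(vars < floor_v)) {
    warning("degenerate feature variance regularized")
    vars <- pmax(vars, floor_v)
  }
  model <- structure(list(selected = selected,
                          feature_names = colnames(features$values)[selected],
                          classes = classes, means = means, vars = vars,
                          priors = rep(1 / length(classes), length(classes))),
                     class = "bci_classifier")
  if (method == "gradient") {
    y <- matrix(0, nrow(x), length(classes))
    keep <- rep(FALSE, nrow(x))
    for (k in seq_along(classes)) { y[rows[[k]], k] <- 1; keep[rows[[k]]] <- TRUE }
    xk <- x[keep, , drop = FALSE]; yk <- y[keep, , drop = FALSE]
    for (it in seq_len(gd_iter)) {
      p <- posterior_matrix(model, xk)
      err <- p - yk                      # d(cross-entropy)/d(log-lik)
      for (k in seq_along(classes)) {
        dm <- sweep(xk, 2, model$means[k, ])
        grad_mu <- colSums(err[, k] * dm / rep(model$vars[k, ],
                                               each = nrow(xk)))
        model$means[k, ] <- model$means[k, ] - gd_lr * grad_mu / nrow(xk)
      }
    }
  }
  p <- posterior_matrix(model, x)
  lab_pred <- classes[max.col(p, ties.method = "first")]
  lab_true <- rep(NA_character_, nrow(x))
  for (k in seq_along(classes)) lab_true[rows[[k]]] <- classes[k]
  ok <- !is.na(lab_true)
  model$train_accuracy <- mean(lab_pred[ok] == lab_true[ok])
  model
}

#' @export
print.bci_classifier <- function(x, ...) {
  cat(sprintf("<bci_classifier> %d classes, %d features, train acc %.1f%%\n",
              length(x$classes), length(x$selected),
              100 * (x$train_accuracy %||% NA)))
  invisible(x)
}

## log-likelihood matrix (rows = samples, cols = classes), diagonal
## Gaussians
loglik_matrix <- function(model, x) {
  ll <- sapply(seq_along(model$classes), function(k) {
    m <- model$means[k, ]; v <- model$vars[k, ]
    -0.5 * colSums((t(x) - m)^2 / v) - 0.5 * sum(log(2 * pi * v))
  })
  matrix(ll, nrow = nrow(x))
}

#' Posterior probabilities for a block of feature vectors
#'
#' @param model a [train_classifier()] model.
#' @param x matrix of feature vectors (rows), on the model's selected
#'   features.
#' @return matrix of class posteriors, rows summing to 1.
#' @export
posterior_matrix <- function(model, x) {
  x <- matrix(x, ncol = ncol(model$means))
  ll <- loglik_matrix(model, x) +
    rep(log(model$priors), each = nrow(x))
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  p / rowSums(p)
}

#' Classify a single feature vector
#'
#' @param model a [train_classifier()] model.
#' @param x numeric feature vector matching the model's selected
#'   features.
#' @return named posterior vector over classes (sums to 1).
#' @export
classify_sample <- function(model, x) {
  if (length(x) != ncol(model$means))
    stop("shape error: feature vector length does not match model")
  p <- posterior_matrix(model, matrix(x, 1))[1, ]
  names(p) <- model$classes
  p
}

#' Fresh integrator state
#'
#' @param n_classes number of classes.
#' @return list with the integrated probabilities `I` (uniform), and the
#'   refractory bookkeeping.
#' @export
integrator_state <- function(n_classes = 2) {
  list(I = rep(1 / n_classes, n_classes),
       refractory_until = -Inf, pending_reset = FALSE)
}

#' One evidence-accumulation step
#'
#' Rejects uncertain posteriors (`max(p) < rejection`), otherwise applies
#' the leaky integrator `I' = alpha I + (1 - alpha) p`. When some class's
#' integrated probability reaches its decision threshold, the refractory
#' period has elapsed and the output is not gated by an artifact, a
#' decision is emitted and `I` is reset to the uniform distribution.
#'
#' @param state an [integrator_state()].
#' @param p posterior vector (must sum to 1).
#' @param cfg a [decoder_config()].
#' @param t current time, seconds.
#' @param gated logical: artifact gate active (suppresses emission).
#' @return list with the updated `state` and `decision` (`NULL`, or a
#'   list with `time`, `class` index and the triggering integrated
#'   probability).
#' @export
step_integrator <- function(state, p, cfg, t = 0, gated = FALSE) {
  nc <- length(state$I)
  if (abs(sum(p) - 1) > 1e-6 || any(p < 0))
    stop("contract error: p is not a probability distribution")
  in_refractory <- t < state$refractory_until
  if (cfg$refractory_mode == "freeze" && in_refractory)
    return(list(state = state, decision = NULL))
  if (state$pending_reset && !in_refractory) {
    state$I <- rep(1 / nc, nc)
    state$pending_reset <- FALSE
  }
  if (max(p) < cfg$rejection)           # rejected sample: state frozen
    return(list(state = state, decision = NULL))
  state$I <- cfg$alpha * state$I + (1 - cfg$alpha) * p
  decision <- NULL
  if (!in_refractory && !gated) {
    th <- rep(cfg$thresholds, length.out = nc)
    hit <- which(state$I >= th)
    if (length(hit) > 0) {
      win <- hit[order(-state$I[hit], hit)][1]
      decision <- list(time = t, class = win, prob = state$I[win])
      state$refractory_until <- t + cfg$refractory_s
      state$I <- rep(1 / nc, nc)
      state$pending_reset <- cfg$refractory_mode == "reset"
    }
  }
  list(state = state, decision = decision)
}

#' Run the decoder over a feature stream
#'
#' Classifies every window, accumulates evidence and emits decisions
#' subject to rejection, per-class thresholds, the refractory period and
#' artifact gating.
#'
#' @param features a [feature_matrix] stream (its `window_times` clock
#'   the steps).
#' @param model a [train_classifier()] model.
#' @param cfg a [decoder_config()].
#' @param gate_intervals optional 2-column matrix of `[onset, offset)`
#'   gated intervals in seconds (see [gated_intervals()]).
#' @param keep_trace keep the integrated-probability trace as an
#'   attribute.
#' @return data.frame of decisions: `time`, `class`, `prob`.
#' @export
run_decoder <- function(features, model, cfg = decoder_config(),
                        gate_intervals = NULL, keep_trace = FALSE) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$values[, model$selected, drop = FALSE]
  post <- posterior_matrix(model, x)
  times <- features$window_times
  gated <- rep(FALSE, length(times))
  if (!is.null(gate_intervals) && nrow(gate_intervals) > 0)
    for (i in seq_len(nrow(gate_intervals)))
      gated <- gated | (times >= gate_intervals[i, 1] &
                        times < gate_intervals[i, 2])
  st <- integrator_state(length(model$classes))
  dec_t <- numeric(0); dec_c <- integer(0); dec_p <- numeric(0)
  trace <- if (keep_trace) matrix(NA_real_, length(times),
                                  length(model$classes))
  for (i in seq_along(times)) {
    r <- step_integrator(st, post[i, ], cfg, times[i], gated[i])
    st <- r$state
    if (keep_trace) trace[i, ] <- st$I
    if (!is.null(r$decision)) {
      dec_t <- c(dec_t, r$decision$time)
      dec_c <- c(dec_c, r$decision$class)
      dec_p <- c(dec_p, r$decision$prob)
    }
  }
  out <- data.frame(time = dec_t, class = model$classes[dec_c],
                    prob = dec_p, stringsAsFactors = FALSE)
  if (keep_trace) attr(out, "trace") <- trace
  out
}
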