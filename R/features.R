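## Spatiospectral feature extraction: Laplacian spatial filtering, Welch
## band power on the online 62.5 ms grid, and class-separability maps.

#' Laplacian spatial filter
#'
#' Subtracts from each channel the mean of its montage neighbors,
#' sharpening local activity. Channels with an empty neighbor list pass
#' through unchanged.
#'
#' @param eeg an [eeg_recording()].
#' @param map named list of neighbor labels per channel; defaults to the
#'   orthogonal nearest-neighbor map of the shipped montage.
#' @return filtered [eeg_recording()].
#' @export
laplacian_filter <- function(eeg, map = default_laplacian(eeg$channels)) {
  stopifnot(inherits(eeg, "eeg_recording"))
  known <- unique(c(names(map), unlist(map)))
  if (!all(known %in% eeg$channels))
    stop("montage error: unknown channel in Laplacian map: ",
         paste(setdiff(known, eeg$channels), collapse = ", "))
  out <- eeg$samples
  for (ch in names(map)) {
    nb <- map[[ch]]
    if (length(nb) == 0) next
    out[, ch] <- eeg$samples[, ch] -
      rowMeans(eeg$samples[, nb, drop = FALSE])
  }
  eeg_recording(out, eeg$fs, eeg$channels, eeg$start_time)
}

#' Feature-matrix container
#'
#' Windows x features array of (log) band power. Usually built by
#' [welch_band_power()], but can be assembled directly (e.g. for
#' simulated feature streams). `features` maps each column to a
#' (channel, band bin) pair, `window_times` holds window end times in
#' seconds, and `labels` (optional) the class of each window.
#'
#' @param values numeric windows x features matrix.
#' @param features data.frame with `channel` and `band` per column.
#' @param window_times window end times, seconds (defaults to the
#'   62.5 ms grid).
#' @param labels optional character class per window.
#' @param log10_power whether `values` are log10 band power.
#' @param step_s window step, seconds.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, features,
                           window_times = seq_len(nrow(values)) * STEP_S,
                           labels = NULL, log10_power = TRUE,
                           step_s = STEP_S) {
  values <- as.matrix(values)
  features <- as.data.frame(features)
  if (ncol(values) != nrow(features))
    stop("one feature-index row per column required")
  if (length(window_times) != nrow(values))
    stop("one window time per row required")
  if (!is.null(labels) && length(labels) != nrow(values))
    stop("one label per window required")
  colnames(values) <- paste0(features$channel, "_", features$band)
  new_feature_matrix(values, window_times, features, labels,
                     log10_power, step_s)
}

new_feature_matrix <- function(values, window_times, features, labels,
                               log10_power, step_s) {
  structure(list(values = values, window_times = window_times,
                 features = features, labels = labels,
                 log10_power = log10_power, step_s = step_s),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%s power)\n",
              nrow(x$values), ncol(x$values),
              if (x$log10_power) "log10" else "raw"))
  invisible(x)
}

#' Welch band-power features on a sliding window
#'
#' Power spectral density (Welch periodogram) of each channel with 2 Hz
#' resolution in 1 s windows sliding every 62.5 ms: each window is split
#' into 0.5 s Hann sub-segments with 50% overlap (three per window) and
#' their periodograms averaged. The number of windows is
#' `floor((T - window_s) / step_s) + 1`.
#'
#' @param eeg an [eeg_recording()].
#' @param window_s window length, seconds.
#' @param step_s window step, seconds.
#' @param resolution_hz spectral resolution (bin spacing), Hz.
#' @param fmax_hz highest bin label retained, Hz.
#' @param log10_power if `TRUE` (default) features are log10 band power.
#' @param labels optional [run_labels()]; windows fully inside an
#'   interval inherit its class, others get `NA`.
#' @param channels optional subset of channels to featurize (montage
#'   order is preserved).
#' @return a [feature_matrix] object.
#' @export
welch_band_power <- function(eeg, window_s = 1.0, step_s = STEP_S,
                             resolution_hz = 2, fmax_hz = 48,
                             log10_power = TRUE, labels = NULL,
                             channels = NULL) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (!is.null(channels)) {
    keep <- eeg$channels %in% channels
    eeg <- eeg_recording(eeg$samples[, keep, drop = FALSE], eeg$fs,
                         eeg$channels[keep], eeg$start_time)
  }
  fs <- eeg$fs
  nwin <- round(window_s * fs)
  nseg <- round(fs / resolution_hz)
  hop <- nseg %/% 2
  step <- round(step_s * fs)
  if (step <= 0 || nseg > nwin)
    stop("window must be at least one sub-segment long")
  n <- nrow(eeg$samples)
  nw <- floor((n - nwin) / step) + 1
  bins <- seq(resolution_hz, fmax_hz, by = resolution_hz)
  kidx <- bins / (fs / nseg) + 1   # FFT row per retained bin
  features <- data.frame(
    channel = rep(eeg$channels, each = length(bins)),
    band = rep(bins, length(eeg$channels)), stringsAsFactors = FALSE)
  if (nw < 1) {
    warning("recording shorter than one window; empty feature matrix")
    return(new_feature_matrix(
      matrix(0, 0, nrow(features)), numeric(0), features, NULL,
      log10_power, step_s))
  }
  nsub <- (nwin - nseg) %/% hop + 1
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / nseg)  # Hann
  U <- sum(win^2)
  ## all sub-segment start samples lie on the step grid (hop multiple of
  ## step); compute every grid periodogram once per channel
  gmax <- (nw - 1) * step + (nsub - 1) * hop + 1
  gstarts <- seq(1, gmax, by = step)
  seg_index <- outer(0:(nseg - 1), gstarts, "+")
  wincols <- outer((0:(nsub - 1)) * (hop %/% step), seq_len(nw), "+")
  ## real DFT restricted to the retained bins (much cheaper than a full
  ## FFT when only a few 2 Hz bins are kept)
  ang <- outer(2 * pi * (kidx - 1) / nseg, 0:(nseg - 1))
  Cm <- cos(ang); Sm <- sin(ang)
  vals <- matrix(0, nw, nrow(features))
  for (j in seq_along(eeg$channels)) {
    segs <- matrix(eeg$samples[, j][seg_index], nrow = nseg) * win
    P <- ((Cm %*% segs)^2 + (Sm %*% segs)^2) * (2 / (fs * U))
    Pb <- P * resolution_hz                      # power per 2 Hz bin
    cols <- (j - 1) * length(bins) + seq_along(bins)
    ## average the nsub sub-segments of each window
    acc <- Pb[, wincols[1, ], drop = FALSE]
    for (m in 2:nsub) acc <- acc + Pb[, wincols[m, ], drop = FALSE]
    vals[, cols] <- t(acc / nsub)
  }
  if (log10_power) vals <- log10(vals)
  colnames(vals) <- paste0(features$channel, "_", features$band)
  wt <- (seq_len(nw) - 1) * step_s + window_s + eeg$start_time
  lab <- NULL
  if (!is.null(labels)) {
    ws <- wt - window_s
    lab <- rep(NA_character_, nw)
    for (i in seq_len(nrow(labels))) {
      inside <- ws >= labels$start[i] - 1e-9 & wt <= labels$end[i] + 1e-9
      lab[inside] <- labels$class[i]
    }
  }
  new_feature_matrix(vals, wt, features, lab, log10_power, step_s)
}

#' Fisher score of one feature between two classes
#'
#' `FS = |mu1 - mu2| / sqrt(s1^2 + s2^2)` with sample (n - 1) variances.
#' Zero when both classes are identical; `Inf` (with a warning) when both
#' variances vanish but the means differ.
#'
#' @param x1,x2 numeric sample vectors, one per class (>= 2 values each).
#' @return non-negative scalar.
#' @export
fisher_score <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("need at least 2 samples per class")
  v <- var(x1) + var(x2)
  d <- abs(mean(x1) - mean(x2))
  if (v == 0) {
    if (d == 0) return(0)
    warning("zero within-class variance with distinct means")
    return(Inf)
  }
  d / sqrt(v)
}

## column-wise means/vars for a subset of rows
col_stats <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- (colSums(x^2) - n * m^2) / (n - 1)
  list(mean = m, var = pmax(v, 0), n = n)
}

#' Channel x band discriminancy map
#'
#' Fisher score of every (channel, band) feature between the two
#' motor-imagery classes, over all labeled windows (windows labeled
#' `rest` or unlabeled are excluded).
#'
#' @param features a [feature_matrix] with labels.
#' @param classes the two class names to contrast.
#' @return object of class `discriminancy_map`: a channels x bands
#'   matrix `fs` plus the class pair and per-class window counts.
#' @export
discriminancy_map <- function(features,
                              classes = c("both_hands", "both_feet")) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(features$labels)) stop("insufficient data: no labels")
  i1 <- which(features$labels %in% classes[1])
  i2 <- which(features$labels %in% classes[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("insufficient data: both classes must be present")
  s1 <- col_stats(features$values[i1, , drop = FALSE])
  s2 <- col_stats(features$values[i2, , drop = FALSE])
  v <- s1$var + s2$var
  fs <- ifelse(v > 0, abs(s1$mean - s2$mean) / sqrt(v),
               ifelse(s1$mean == s2$mean, 0, Inf))
  channels <- unique(features$features$channel)
  bands <- sort(unique(features$features$band))
  m <- matrix(NA_real_, length(channels), length(bands),
              dimnames = list(channels, bands))
  m[cbind(match(features$features$channel, channels),
          match(features$features$band, bands))] <- fs
  structure(list(fs = m, classes = classes,
                 n_windows = c(length(i1), length(i2))),
            class = "discriminancy_map")
}

#' @export
print.discriminancy_map <- function(x, ...) {
  cat(sprintf("<discriminancy_map> %s vs %s (%d/%d windows)\n",
              x$classes[1], x$classes[2], x$n_windows[1], x$n_windows[2]))
  cat(sprintf("  peak FS %.3f at %s\n", max(x$fs),
              paste(rownames(x$fs)[which(x$fs == max(x$fs),
                                         arr.ind = TRUE)[1, 1]],
                    colnames(x$fs)[which(x$fs == max(x$fs),
                                         arr.ind = TRUE)[1, 2]], "Hz")))
  invisible(x)
}

#' Mean discriminancy over a topographic/spectral region
#'
#' Arithmetic mean of the Fisher scores of all (channel, band) cells in
#' the region (e.g. medial beta = 3 channels x 6 bins = 18 cells).
#'
#' @param map a [discriminancy_map()].
#' @param region a [region_spec()].
#' @return scalar mean Fisher score.
#' @export
region_discriminancy <- function(map, region) {
  stopifnot(inherits(map, "discriminancy_map"),
            inherits(region, "region_spec"))
  ch <- intersect(region$channels, rownames(map$fs))
  bn <- intersect(as.character(region$bins), colnames(map$fs))
  if (length(ch) == 0 || length(bn) == 0)
    stop("invalid region: no matching channels/bands in map")
  mean(map$fs[ch, bn])
}

#' Rank spatiospectral features by discriminant power (CVA)
#'
#' Two-class canonical variate analysis reduced to the Fisher linear
#' discriminant eigenproblem: the canonical direction is
#' `w = Sw^-1 (m1 - m2)` with shrinkage-regularized pooled within-class
#' covariance. Each feature's discriminant power is `|w_i| *
#' sqrt(Sw_ii)`; for uncorrelated features this is proportional to the
#' per-feature Fisher criterion. Ties are broken by lower feature index.
#'
#' @param features a labeled [feature_matrix].
#' @param classes the two classes.
#' @param shrinkage relative diagonal loading added to the pooled
#'   covariance (increased automatically if it is singular, flagged via
#'   the `regularized` attribute).
#' @return data.frame sorted by decreasing `score`, with columns
#'   `feature` (column index), `channel`, `band`, `score`.
#' @export
cva_rank_features <- function(features,
                              classes = c("both_hands", "both_feet"),
                              shrinkage = 1e-3) {
  stopifnot(inherits(features, "feature_matrix"))
  i1 <- which(features$labels %in% classes[1])
  i2 <- which(features$labels %in% classes[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("insufficient data: both classes must be present")
  x1 <- features$values[i1, , drop = FALSE]
  x2 <- features$values[i2, , drop = FALSE]
  d <- colMeans(x1) - colMeans(x2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  sw <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) /
    (n1 + n2 - 2)
  lam <- shrinkage * mean(diag(sw))
  regularized <- FALSE
  repeat {
    sreg <- sw + diag(lam, ncol(sw))
    w <- tryCatch(solve(sreg, d), error = function(e) NULL)
    if (!is.null(w)) break
    regularized <- TRUE
    lam <- lam * 10
  }
  if (lam > shrinkage * mean(diag(sw))) regularized <- TRUE
  score <- abs(w) * sqrt(diag(sreg))
  ## snap floating-point near-ties so equal-information features (e.g.
  ## duplicated columns) deterministically break toward the lower index
  ord <- order(-signif(score, 8), seq_along(score))
  out <- data.frame(feature = ord,
                    channel = features$features$channel[ord],
                    band = features$features$band[ord],
                    score = score[ord], stringsAsFactors = FALSE)
  attr(out, "regularized") <- regularized
  out
}
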