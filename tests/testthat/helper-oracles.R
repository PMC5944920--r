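# Independent oracles used across the suite.

# Pearson r and two-sided t-test p computed from first principles.
brute_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Exact two-sided rank-sum p by full enumeration of rank assignments
# (no ties assumed). Feasible for n1 + n2 <= 12 or so.
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  all_ranks <- seq_len(n1 + n2)
  w_null <- apply(combos, 2, function(i) sum(all_ranks[i]))
  mu <- n1 * (n1 + n2 + 1) / 2
  mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-9)
}

# Closed-form crossing time of a single pad with one regime switch at
# elapsed time u after entry (both regimes given as time-to-cross).
switch_crossing_time <- function(u, t_first, t_second) {
  frac <- u / t_first
  u + (1 - frac) * t_second
}

# Toy three-channel feature matrix with two Gaussian classes.
toy_features <- function(n_per_class = 200, delta = c(2, 0, 0), sd = 1,
                         classes = c("both_hands", "both_feet")) {
  nf <- length(delta)
  x1 <- matrix(rnorm(n_per_class * nf, 0, sd), ncol = nf)
  x2 <- matrix(rnorm(n_per_class * nf, 0, sd), ncol = nf)
  x2 <- sweep(x2, 2, delta, "+")
  feature_matrix(rbind(x1, x2),
                 features = data.frame(channel = paste0("C", seq_len(nf)),
                                       band = 24),
                 labels = rep(classes, each = n_per_class))
}
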