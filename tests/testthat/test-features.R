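toy_eeg <- function(samples, channels, fs = 512) {
  eeg_recording(samples, fs, channels)
}

test_that("Laplacian filter matches hand computation on a toy montage", {
  map <- list(A = "B", B = c("A", "C"), C = "B")
  ## single nonzero channel keeps its value; neighbors subtract shares
  x <- cbind(A = rep(4, 10), B = rep(0, 10), C = rep(0, 10))
  out <- laplacian_filter(toy_eeg(x, c("A", "B", "C")), map)
  expect_equal(unname(out$samples[1, ]), c(4, -2, 0))
  ## common mode: identical constant on all channels vanishes
  y <- cbind(A = rep(7, 10), B = rep(7, 10), C = rep(7, 10))
  out2 <- laplacian_filter(toy_eeg(y, c("A", "B", "C")), map)
  expect_equal(max(abs(out2$samples)), 0)
  ## adding a constant to all channels leaves output unchanged
  z <- matrix(rnorm(30), 10, 3)
  e1 <- laplacian_filter(toy_eeg(z, c("A", "B", "C")), map)
  e2 <- laplacian_filter(toy_eeg(z + 5, c("A", "B", "C")), map)
  expect_equal(e1$samples, e2$samples)
  ## empty map is the identity; unknown channel errors
  expect_equal(laplacian_filter(toy_eeg(z, c("A", "B", "C")),
                                list())$samples,
               toy_eeg(z, c("A", "B", "C"))$samples)
  expect_error(laplacian_filter(toy_eeg(z, c("A", "B", "C")),
                                list(A = "Q")), "montage")
})

test_that("window count follows the sliding-window formula", {
  for (T in c(1, 2.5, 10, 13.0625)) {
    eeg <- toy_eeg(matrix(rnorm(T * 512), ncol = 1), "Cz")
    f <- welch_band_power(eeg)
    expect_equal(nrow(f$values), floor((T - 1) / 0.0625) + 1)
  }
  ## T = 10 s: 145 windows
  eeg <- toy_eeg(matrix(rnorm(5120), ncol = 1), "Cz")
  expect_equal(nrow(welch_band_power(eeg)$values), 145)
  ## shorter than one window: empty with warning
  short <- toy_eeg(matrix(rnorm(256), ncol = 1), "Cz")
  expect_warning(f0 <- welch_band_power(short), "shorter")
  expect_equal(nrow(f0$values), 0)
})

test_that("a pure 24 Hz sinusoid peaks in the 24 Hz bin in every window", {
  t <- (0:(512 * 4 - 1)) / 512
  eeg <- toy_eeg(matrix(20 * sin(2 * pi * 24 * t), ncol = 1), "Cz")
  f <- welch_band_power(eeg)
  peaks <- f$features$band[apply(f$values, 1, which.max)]
  expect_true(all(peaks == 24))
})

test_that("white noise gives a flat spectrum across bins", {
  set.seed(2)
  eeg <- toy_eeg(matrix(rnorm(512 * 240), ncol = 1), "Cz")
  f <- welch_band_power(eeg, log10_power = FALSE)
  mean_power <- colMeans(f$values)
  ## ~4 sigma of the Monte-Carlo error of per-bin means at this length
  expect_lt(max(abs(mean_power / mean(mean_power) - 1)), 0.15)
})

test_that("fisher_score matches closed-form and hand-computed values", {
  expect_equal(fisher_score(c(1, 1, 1), c(1, 1, 1)), 0)
  ## mu1 = 1, mu2 = 0, s1 = s2 = 1 -> 1/sqrt(2); samples engineered to
  ## have exactly those moments
  x1 <- c(0, 1, 2); x2 <- c(-1, 0, 1)   # mean 1 / 0, sd 1 / 1
  expect_equal(fisher_score(x1, x2), 1 / sqrt(2))
  ## hand computation with the n - 1 variance convention
  expect_equal(fisher_score(c(1, 2, 3, 4), c(3, 4, 5, 6)),
               2 / sqrt(10 / 3), tolerance = 1e-12)
  ## degenerate cases
  expect_warning(fs <- fisher_score(c(1, 1), c(2, 2)), "variance")
  expect_identical(fs, Inf)
})

test_that("Fisher score is symmetric and affine invariant", {
  set.seed(3)
  for (i in 1:20) {
    x1 <- rnorm(30); x2 <- rnorm(30, 1)
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    b <- runif(1, -10, 10)
    expect_equal(fisher_score(x1, x2), fisher_score(x2, x1))
    expect_equal(fisher_score(a * x1 + b, a * x2 + b),
                 fisher_score(x1, x2), tolerance = 1e-10)
  }
})

test_that("discriminancy map localizes a planted effect and is symmetric", {
  cfg <- synth_config(channels = c("C3", "Cz", "C4"),
                      effect_channels = "Cz", effect_size = 1,
                      trial_schedule = alternating_schedule(5, 24),
                      seed = 7)
  run <- generate_run(cfg)
  f <- welch_band_power(run$eeg, labels = run$labels)
  dm <- discriminancy_map(f)
  beta <- as.character(seq(22, 32, 2))
  expect_equal(rownames(dm$fs)[which.max(rowMeans(dm$fs[, beta]))], "Cz")
  ## class-swap symmetry
  dm2 <- discriminancy_map(f, classes = c("both_feet", "both_hands"))
  expect_equal(dm$fs, dm2$fs)
  ## identical features relabeled -> all-zero map
  v <- matrix(rnorm(40), 20, 2)
  fm <- feature_matrix(rbind(v, v),
                       features = data.frame(channel = c("C3", "Cz"),
                                             band = 24),
                       labels = rep(c("both_hands", "both_feet"),
                                    each = 20))
  expect_true(all(discriminancy_map(fm)$fs == 0))
})

test_that("random label shuffling collapses the map toward the null", {
  cfg <- synth_config(channels = c("Cz"), effect_channels = "Cz",
                      effect_size = 1,
                      trial_schedule = alternating_schedule(5, 24),
                      seed = 9)
  run <- generate_run(cfg)
  f <- welch_band_power(run$eeg, labels = run$labels)
  real <- mean(discriminancy_map(f)$fs[, as.character(seq(22, 32, 2))])
  set.seed(1)
  f$labels <- sample(f$labels)
  shuffled <- mean(discriminancy_map(f)$fs[, as.character(seq(22, 32, 2))])
  expect_lt(shuffled, real / 3)
})

test_that("region discriminancy averages the expected cells", {
  channels <- default_montage()
  bands <- seq(2, 48, 2)
  feats <- data.frame(channel = rep(channels, each = length(bands)),
                      band = rep(bands, length(channels)))
  set.seed(4)
  fm <- feature_matrix(matrix(rnorm(40 * nrow(feats)), 40),
                       features = feats,
                       labels = rep(c("both_hands", "both_feet"), 20))
  dm <- discriminancy_map(fm)
  med <- region_spec("medial", "beta")
  ## medial beta = 3 channels x 6 bins = 18 cells, plain mean
  cells <- dm$fs[c("FCz", "Cz", "CPz"), as.character(seq(22, 32, 2))]
  expect_equal(length(cells), 18)
  expect_equal(region_discriminancy(dm, med), mean(cells))
  ## constant map returns the constant
  dm$fs[] <- 0.42
  expect_equal(region_discriminancy(dm, region_spec("lateral", "mu")), 0.42)
})

test_that("CVA ranks a planted discriminative feature first", {
  set.seed(5)
  fm <- toy_features(n_per_class = 150, delta = c(0, 1.5, 0, 0, 0))
  rk <- cva_rank_features(fm)
  expect_equal(rk$feature[1], 2)
  ## duplicated feature column: tie broken by lower index
  v <- fm$values
  v[, 3] <- v[, 2]
  fm2 <- feature_matrix(v, fm$features, labels = fm$labels)
  rk2 <- cva_rank_features(fm2)
  dup <- rk2$feature[rk2$feature %in% c(2, 3)]
  expect_equal(dup, c(2, 3))
})

test_that("CVA top score under the null is unremarkable against permutations", {
  set.seed(6)
  fm <- toy_features(n_per_class = 80, delta = rep(0, 4))
  top <- cva_rank_features(fm)$score[1]
  perm_tops <- replicate(50, {
    f2 <- fm
    f2$labels <- sample(fm$labels)
    cva_rank_features(f2)$score[1]
  })
  ## observed top score within the permutation null distribution
  expect_gt(mean(perm_tops >= top), 0.05)
})
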