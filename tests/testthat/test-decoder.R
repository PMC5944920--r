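test_that("classifier separates well-separated clouds and stays calibrated", {
  set.seed(1)
  ## d' = 6: means 6 sd apart on one feature
  fm <- toy_features(n_per_class = 300, delta = c(6, 0))
  m <- train_classifier(fm, 1:2)
  expect_gte(m$train_accuracy, 0.99)
  ## posteriors are proper probabilities
  p <- posterior_matrix(m, fm$values)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  ## identical class distributions: chance accuracy
  fm0 <- toy_features(n_per_class = 300, delta = c(0, 0))
  m0 <- train_classifier(fm0, 1:2)
  expect_gt(m0$train_accuracy, 0.40)
  expect_lt(m0$train_accuracy, 0.60)
  ## one class absent
  fm1 <- fm; fm1$labels <- rep("both_hands", length(fm$labels))
  expect_error(train_classifier(fm1, 1:2), "training error")
})

test_that("posteriors respect symmetry and likelihood dominance", {
  m <- structure(list(selected = 1:2, classes = c("a", "b"),
                      means = rbind(c(-2, 0), c(2, 0)),
                      vars = rbind(c(1, 1), c(1, 1)),
                      priors = c(0.5, 0.5)),
                 class = "bci_classifier")
  ## midpoint of symmetric classes
  expect_equal(unname(classify_sample(m, c(0, 0))), c(0.5, 0.5))
  ## at a far-separated class mean
  expect_gt(classify_sample(m, c(-2, 0))["a"], 0.99)
  ## prior scaling invariance: posteriors unchanged if both likelihoods
  ## are scaled (shift both means by the same amount along the shared
  ## null axis)
  expect_equal(classify_sample(m, c(1, 5)), classify_sample(m, c(1, -5)))
  expect_error(classify_sample(m, c(1, 2, 3)), "shape")
})

test_that("gradient refinement preserves calibration and accuracy", {
  set.seed(8)
  fm <- toy_features(n_per_class = 200, delta = c(2, 1))
  m <- train_classifier(fm, 1:2, method = "gradient")
  p <- posterior_matrix(m, fm$values)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  m0 <- train_classifier(fm, 1:2)
  expect_gte(m$train_accuracy, m0$train_accuracy - 0.02)
})

test_that("time to decision matches the geometric closed form", {
  run_until_decision <- function(cfg, p, max_steps = 200) {
    st <- integrator_state(2)
    for (n in seq_len(max_steps)) {
      r <- step_integrator(st, p, cfg, t = n * 0.0625)
      st <- r$state
      if (!is.null(r$decision)) return(list(step = n, d = r$decision))
    }
    list(step = NA_integer_, d = NULL)
  }
  ## I_n = 1 - 0.5 alpha^n >= 0.9 first at n = 40 for alpha = 0.96
  cfg <- decoder_config(rejection = 0, alpha = 0.96, thresholds = 0.9)
  r <- run_until_decision(cfg, c(1, 0))
  expect_equal(r$step, 40)
  expect_equal(r$d$class, 1)
  ## I_n = 0.9 - 0.4 alpha^n >= 0.85 first at n = 51
  cfg2 <- decoder_config(rejection = 0, alpha = 0.96, thresholds = 0.85)
  expect_equal(run_until_decision(cfg2, c(0.9, 0.1))$step, 51)
  ## constant posterior below threshold: never decides
  expect_true(is.na(run_until_decision(cfg, c(0.85, 0.15))$step))
  ## uniform posterior: integrator stays uniform
  st <- integrator_state(2)
  for (n in 1:50) st <- step_integrator(st, c(0.5, 0.5), cfg,
                                        n * 0.0625)$state
  expect_equal(st$I, c(0.5, 0.5))
})

test_that("monotone convergence of the integrator follows I_n = p + (I0 - p) a^n", {
  cfg <- decoder_config(rejection = 0, alpha = 0.9, thresholds = 1.0)
  st <- integrator_state(2)
  p <- c(0.8, 0.2)
  for (n in 1:30) {
    st <- step_integrator(st, p, cfg, n * 0.0625)$state
    expect_equal(st$I[1], 0.8 + (0.5 - 0.8) * 0.9^n, tolerance = 1e-12)
  }
})

test_that("rejection saturation freezes the state", {
  expect_warning(cfg <- decoder_config(rejection = 1, thresholds = 0.9),
                 "rejected")
  st <- integrator_state(2)
  for (n in 1:100) {
    r <- step_integrator(st, c(0.99, 0.01), cfg, n * 0.0625)
    st <- r$state
    expect_null(r$decision)
  }
  expect_equal(st$I, c(0.5, 0.5))
})

test_that("run_decoder emits ordered class decisions with refractory spacing", {
  m <- structure(list(selected = 1, classes = c("both_hands", "both_feet"),
                      means = rbind(-2, 2), vars = rbind(0.25, 0.25),
                      priors = c(0.5, 0.5)),
                 class = "bci_classifier")
  set.seed(2)
  vals <- matrix(c(rnorm(160, -2, 0.5), rnorm(160, 2, 0.5)), ncol = 1)
  fm <- feature_matrix(vals, data.frame(channel = "Cz", band = 24))
  dec <- run_decoder(fm, m, decoder_config())
  expect_gt(nrow(dec), 1)
  expect_true(any(dec$class == "both_hands") &&
              any(dec$class == "both_feet"))
  expect_lt(max(which(dec$class == "both_hands")),
            min(which(dec$class == "both_feet")))
  if (nrow(dec) > 1)
    expect_true(all(diff(dec$time) >= 1.0 - 1e-9))
  ## artifact gate covering the whole run: zero decisions
  dec0 <- run_decoder(fm, m, decoder_config(),
                      gate_intervals = cbind(0, 1e6))
  expect_equal(nrow(dec0), 0)
})

test_that("fuzzed streams never violate simplex, refractory or gating", {
  set.seed(3)
  cfg <- decoder_config()
  n_steps <- 1e5
  gates <- cbind(onset = c(100, 400) * 0.0625,
                 offset = c(160, 470) * 0.0625)
  st <- integrator_state(2)
  last_t <- -Inf
  simplex_bad <- 0L; gate_bad <- 0L; refractory_bad <- 0L
  qs <- runif(n_steps)
  for (n in seq_len(n_steps)) {
    t <- n * 0.0625
    gated <- any(t >= gates[, 1] & t < gates[, 2])
    r <- step_integrator(st, c(qs[n], 1 - qs[n]), cfg, t, gated)
    st <- r$state
    if (abs(sum(st$I) - 1) > 1e-9 || any(st$I < 0))
      simplex_bad <- simplex_bad + 1L
    if (!is.null(r$decision)) {
      if (gated) gate_bad <- gate_bad + 1L
      if (t - last_t < cfg$refractory_s - 1e-9)
        refractory_bad <- refractory_bad + 1L
      last_t <- t
    }
  }
  expect_identical(c(simplex_bad, gate_bad, refractory_bad), rep(0L, 3))
})
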