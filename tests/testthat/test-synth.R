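test_that("generation is bit-reproducible for identical config and seed", {
  cfg <- synth_config(channels = c("C3", "Cz", "C4"),
                      effect_channels = "Cz",
                      trial_schedule = alternating_schedule(2, 4),
                      seed = 11)
  a <- generate_run(cfg)
  b <- generate_run(cfg)
  expect_identical(a$eeg$samples, b$eeg$samples)
  expect_identical(a$eog$samples, b$eog$samples)
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(generate_run(cfg2)$eeg$samples, a$eeg$samples))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(effect_band = c(100, 300)), "Nyquist")
  expect_error(synth_config(effect_size = -1), "effect_size")
  expect_error(synth_config(trial_schedule = data.frame(
    class = "both_hands", duration = -5)), "duration")
  expect_error(generate_campaign(synth_config(), numeric(0)), "empty")
  expect_error(generate_campaign(synth_config(), c(0.5, -0.1)), "negative")
})

test_that("null effect yields near-zero Fisher scores everywhere", {
  cfg <- synth_config(channels = c("C3", "Cz"), effect_channels = "Cz",
                      effect_size = 0,
                      trial_schedule = alternating_schedule(5, 48),
                      seed = 5)
  run <- generate_run(cfg)
  f <- welch_band_power(run$eeg, labels = run$labels)
  dm <- discriminancy_map(f)
  expect_lt(mean(dm$fs), 0.12)
  expect_lt(max(dm$fs), 0.35)
})

test_that("measured Fisher score tracks the requested effect size", {
  ## 300 s per class at Cz; interior beta bins (edge bins are slightly
  ## diluted by spectral leakage at the band borders)
  measured <- sapply(c(0.2, 0.5, 1.0), function(es) {
    cfg <- synth_config(channels = c("C3", "Cz", "C4"),
                        effect_channels = "Cz", effect_size = es,
                        trial_schedule = alternating_schedule(5, 120),
                        seed = 21)
    run <- generate_run(cfg)
    f <- welch_band_power(run$eeg, labels = run$labels)
    dm <- discriminancy_map(f)
    mean(dm$fs["Cz", as.character(seq(24, 30, 2))])
  })
  expect_true(all(diff(measured) > 0))
  expect_true(all(abs(measured - c(0.2, 0.5, 1.0)) <
                    0.2 * c(0.2, 0.5, 1.0) + 0.04))
})

test_that("campaign recovers a programmed discriminancy trend", {
  cfg <- synth_config(channels = c("C3", "Cz", "C4"),
                      effect_channels = "Cz",
                      trial_schedule = alternating_schedule(5, 12),
                      seed = 31)
  runs <- generate_campaign(cfg, seq(0.1, 0.6, length.out = 20))
  disc <- sapply(runs, function(r) {
    f <- welch_band_power(r$eeg, labels = r$labels)
    mean(discriminancy_map(f)$fs["Cz", as.character(seq(22, 32, 2))])
  })
  tr <- trend_correlation(disc)
  expect_gt(tr$r, 0)
  expect_lt(tr$p, 0.05)
  ## constant schedule: no programmed learning
  runs0 <- generate_campaign(cfg, rep(0.3, 12))
  disc0 <- sapply(runs0, function(r) {
    f <- welch_band_power(r$eeg, labels = r$labels)
    mean(discriminancy_map(f)$fs["Cz", as.character(seq(22, 32, 2))])
  })
  expect_gt(trend_correlation(disc0)$p, 0.05)
  ## single-entry schedule
  expect_length(generate_campaign(cfg, 0.4), 1)
})

test_that("EOG artifact injection matches its templates", {
  cfg <- synth_config(channels = c("C3", "Cz"), effect_channels = "Cz",
                      trial_schedule = data.frame(class = "rest",
                                                  duration = 10),
                      seed = 41)
  eog <- generate_run(cfg)$eog
  ## empty event list: identity
  expect_identical(inject_eog_artifacts(eog, data.frame()), eog)
  ## horizontal saccade: |EOG_h| peak dominates |EOG_v| around t = 3
  ev <- data.frame(time = 3, kind = "saccade_h", amplitude = 150)
  d <- derive_eog_channels(inject_eog_artifacts(eog, ev))
  win <- (3 * 512):(3.4 * 512)
  expect_gt(max(abs(d$samples[win, "EOG_h"])),
            max(abs(d$samples[win, "EOG_v"])))
  ## out-of-span event
  expect_error(inject_eog_artifacts(
    eog, data.frame(time = 99, kind = "blink", amplitude = 100)),
    "span")
})

test_that("an injected blink is detected within 125 ms of its onset", {
  cfg <- synth_config(channels = c("C3", "Cz"), effect_channels = "Cz",
                      trial_schedule = data.frame(class = "rest",
                                                  duration = 10),
                      seed = 43)
  eog <- generate_run(cfg)$eog
  eog <- inject_eog_artifacts(
    eog, data.frame(time = 5, kind = "blink", amplitude = 200))
  gate <- artifact_gate(eog)
  onsets <- gate$events$time[gate$events$kind == "onset"]
  expect_true(any(abs(onsets - 5) <= 0.125))
})
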