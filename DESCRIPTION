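Package: bciracer
Title: Closed-Loop Motor-Imagery BCI Decoding and Racing-Game Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation and evaluation toolkit for closed-loop sensorimotor-rhythm
    brain-computer interfaces (BCI) operating a racing game. Provides a synthetic
    EEG/EOG generator with controllable motor-imagery effect size, the full online
    decoding chain (Laplacian spatial filtering, Welch band-power features,
    Fisher-score discriminancy, canonical-variate feature ranking, Gaussian
    classification, leaky-integrator evidence accumulation with rejection,
    decision thresholds and a refractory period), frame-wise EOG artifact
    detection and command gating, the game-control paradigms that map mental
    commands to avatar actions, an exact pad-based race simulator with boost,
    baseline and penalty regimes, and the longitudinal performance and learning
    statistics (command accuracies, pad crossing times, Pearson trend tests and
    rank-sum contrasts) used to study user training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
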