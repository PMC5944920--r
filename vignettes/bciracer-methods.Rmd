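---
title: "bciracer: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bciracer: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bciracer)
```

This vignette documents the models behind `bciracer`, the assumptions
they make, the parameters that matter, and the design decisions taken
where several reasonable implementations existed. The package simulates
the whole closed loop of a two-class motor-imagery (MI) BCI driving a
pad-based racing game, so that longitudinal training phenomena can be
studied on synthetic data with known ground truth.

## 1. The synthetic EEG model

Each channel's background is a stationary Gaussian process with power
spectral density proportional to `max(f, 1 Hz)^-γ` plus a relative white
floor (`γ = 1`, floor `0.05` by default), scaled to a root-mean-square
amplitude of 20 µV. These are conventional EEG-like values: the package
makes no attempt to match any particular subject's amplitude statistics,
and no biophysical forward model is involved.

Sensorimotor-rhythm modulation is implemented as class-dependent
amplitude scaling of the in-band component on the effect channels.
Writing ρ for the band-power ratio between the two MI classes, the band
amplitude is multiplied by ρ^(+1/4) during both-feet imagery (ERS-like
power increase), ρ^(-1/4) during both-hands imagery (ERD-like decrease)
and left untouched at rest. Three properties motivated this symmetric
construction:

* rest sits at the geometric mean of the two class distributions in log
  band power, so a classifier trained on the two MI classes produces
  ambiguous posteriors at rest — which is exactly the mechanism by which
  intentional non-control (INC) works in thresholded evidence-
  accumulation decoders. A one-sided construction (inflating one class
  only) would make rest indistinguishable from the other class and INC
  impossible.
* band-*amplitude* scaling (rather than added sinusoids) matches the
  band-power feature assumption of the decoding chain.
* with every grid channel carrying the same relative modulation (the
  default `effect_channels` is the whole 5 × 3 sensorimotor grid, as
  both-hands-vs-both-feet imagery modulates the entire strip), the
  Laplacian derivation — a linear combination of identically scaled
  components — preserves the band-power ratio exactly, so the
  calibration below survives spatial filtering.

### Effect-size calibration

The generator's `effect_size` is the Fisher score that the log
band-power feature of an effect channel should converge to. For a Welch
band-power estimate distributed like a scaled chi-square with effective
shape `a`, the log estimate has variance `trigamma(a)` independent of
scale, and the two classes differ in mean log power by `log(ρ)`. Hence

    FS = log(ρ) / sqrt(2 · trigamma(a))   ⇒   ρ = exp(FS · sqrt(2 V)),

with `V = trigamma(a)`. For this package's estimator (1 s windows, three
0.5 s Hann sub-segments at 50% overlap) the sub-segment periodograms are
correlated, so `a` was determined numerically: `V = 0.413`
(equivalently `a ≈ 2.89`), frozen as a package constant. The test suite
verifies the resulting end-to-end calibration: requested effect sizes
0.2/0.5/1.0 are recovered within ±20% from 300 s per class, measured on
the interior β bins. The 2 Hz bins at the band edges (22 and 32 Hz)
read a few percent low because the Hann main lobe averages modulated and
unmodulated energy there; calibration tests therefore read the interior
bins, and users mapping small regions should expect the same edge
effect.

A band bin labeled `f` covers `[f − 1, f + 1)` Hz throughout the
package, so the β region 22–32 Hz comprises the six bins 22, 24, …, 32
and `effect_band = c(22, 32)` modulates 21–33 Hz.

### What the generator does not emulate

Volume conduction (channels are independent), realistic EMG spectra,
non-stationarities within a run (fatigue, drifting electrode
impedances), eye-movement leakage into the EEG channels, and any
coupling between artifacts and MI state. Passing tests on this generator
therefore demonstrate correctness of the decoding and evaluation
machinery under the stated model — not performance on real recordings.

## 2. Feature extraction

The Welch periodogram uses 0.5 s Hann sub-segments with 50% overlap
(three per 1 s window), giving exactly 2 Hz bin spacing at 512 Hz; the
window slides every 62.5 ms, the decoder's clock. Only the window
length, step and resolution are externally constrained; the sub-segment
scheme is this package's choice and fixed for reproducibility. Features
are log10 band power by default (`log10_power = FALSE` gives raw
power): the log stabilizes the variance of chi-square-like power
estimates, which both the Fisher score and the Gaussian classifier
assume. Sample variances use the n − 1 convention everywhere.

The Laplacian neighbor map defaults to orthogonal nearest neighbors on
the 5 × 3 grid (e.g. `Cz ↔ {FCz, CPz, C1, C2}`) and ships as an
editable JSON structure (`default_laplacian()`, `read_laplacian()`).

Two-class canonical variate analysis reduces to the Fisher linear
discriminant; features are ranked by `|w_i| · sqrt(Sw_ii)` where `w` is
the shrinkage-regularized discriminant direction. For uncorrelated
features this ordering coincides with the per-feature Fisher criterion,
which the tests exploit as an oracle. Ties break toward the lower
feature index.

## 3. The decoder

Posteriors come from one diagonal-covariance Gaussian prototype per
class with uniform priors, fit in closed form (a gradient-descent
refinement of the means under cross-entropy is available behind a flag;
the closed-form fit is the default because it is exactly reproducible).
Evidence accumulation is exponential smoothing on the probability
simplex, `I' = αI + (1 − α)p` per 62.5 ms step, after discarding samples
whose maximum posterior is below the rejection threshold ρ.

Defaults: α = 0.96, ρ = 0.55, θ = 0.9 per class, 1 s refractory. With a
constant accepted posterior `p = (q, 1 − q)` the integrator follows the
closed form `I_n(1) = q + (1/2 − q)αⁿ`, so time-to-decision is
analytic: from uniform with q = 1, the threshold 0.9 is first reached at
step 40 (2.5 s). This closed form is used as the oracle for the decoder
tests, and it is why these defaults give seconds-scale decisions.

Two semantics were open where only the refractory period's existence is
specified:

* during the refractory period evidence keeps integrating but emission
  is suppressed, and the integrator is re-reset to uniform when the
  period ends (so every decision starts from an unbiased state);
  `refractory_mode = "freeze"` keeps the state frozen instead.
* rejected samples freeze the integrator rather than leaking it toward
  uniform; the alternative is not excluded by the decoder's description
  but freezing is the minimal interpretation.

Artifact gating suppresses emission the same way the refractory period
does; evidence continues to accumulate while gated.

## 4. Artifact detection

Detection is frame-wise and causal: the derived channels (EOG_h, EOG_v
and the mean of the three active sensors — the fourth is the reference)
are filtered 1–10 Hz with an order-2 Butterworth filter applied in a
streaming fashion, rectified, and each 62.5 ms frame is flagged if any
sample exceeds the common threshold (default 25 µV — the threshold is
configurable equipment-dependent tuning). Causal filtering means the
first flagged frame can trail the physical artifact onset by a filter
transient; the tests allow one frame of tolerance. An onset event is
emitted on a 0→1 frame transition while unblocked; the offset comes a
configurable timeout (default 1 s) after the latest onset detection, so
continuing artifacts extend a single blocked interval.

## 5. Race mechanics

The simulator parameterizes pads by time-to-cross per regime rather than
by virtual distances and speeds, because the game's published behavior
is a set of crossing-time bounds, and this parameterization reproduces
all of them simultaneously and exactly:

| scope | ideal | none | penalty |
|---|---|---|---|
| action pad | 2 | 11 | 19 |
| white pad | — | 5.5 | 19 |
| starting white | — | 5 | 13 |
| ending white | — | 3 | 10 |
| standard track | 54 | 162 | 327 |

(12·2 + 4·5.5 + 5 + 3 = 54; 12·11 + 4·5.5 + 5 + 3 = 162;
16·19 + 13 + 10 = 327.) The avatar progresses at `1/t_regime` pad
fractions per second; a correct command boosts until the pad ends or an
erroneous command overrides it; any erroneous command (all commands are
erroneous on white pads) switches to the penalty regime for 4 s, the
timer resetting on further errors and ending early at a correct command
or the pad boundary; regimes reset to base at every pad entry. Crossing
times with mid-pad regime switches follow a piecewise-linear closed form
that the tests use as an oracle against the event-driven simulator. The
240 s competition cap is recorded as a validity flag, not a clamp,
since 327 s is the mechanical bound. Commands take effect exactly at
their timestamps; a command at a pad boundary applies to the new pad.

## 6. Control paradigms

Paradigm 4 (the pair-triggered slide) forwards both constituent
commands as they occur and emits the slide at the second decision of an
alternating pair within the timeout, after which the pair window resets
— whether the real implementation withheld the constituent commands
until the timeout elapsed is not documented, and forwarding is the
reading consistent with commands being sent as produced, with the
game's overriding rule making the net effect a slide. Paradigm 3
re-arms its inactivity timer after every decision *and* every emitted
slide; without re-arming, a long idle stretch would slide only once,
which could not serve yellow pads at arbitrary positions. Windows and
idle periods use half-open `[t, t + Δ)` conventions; a decision exactly
on a boundary belongs to the later window.

## 7. The closed-loop campaign

`run_campaign()` simulates a longitudinal training study. Per run it
(i) generates a 60 s calibration recording (alternating 5 s trials) at
the run's programmed effect size, (ii) extracts features, ranks them,
and trains the classifier on the top 24 (the montage offers 90 modulated
channel–bin cells; two dozen roughly independent features give the
combined separability that makes the fixed integrator defaults reach
decisions within action-pad time frames at moderate effect sizes),
(iii) generates 60 s feature streams per intent (each MI class and
rest; windows are recycled when a race outlasts a stream), and (iv)
races a freshly shuffled standard track truly closed-loop: at each
62.5 ms step the simulated pilot's intent is derived from the pad under
the avatar (matching MI on action pads, rest on whites, alternating
spin/jump on yellow pads to trigger the pair slide), one window of the
corresponding stream drives the decoder, and emitted commands feed back
into the race immediately.

The campaign's paradigm-4 pair timeout defaults to 6 s rather than the
paradigm constructor's generic 2 s: the refractory period (1 s) plus
the analytic time-to-decision from uniform (~2.9 s at the default α and
θ even under perfect posteriors) makes a 2 s pair infeasible, so the
timeout must exceed roughly 4 s for the slide strategy to be physically
possible. This was fixed from the closed-form latency, not tuned on
outcomes. Classifier retraining happens every run — a simplification of
occasional recalibration — so decoding quality tracks the programmed
effect size run by run.

Problem sizes used by the shipped tests: module tests use runs of
30–600 s on 1–3 channels; the longitudinal acceptance check runs twenty
20-run campaigns at the defaults above (60 s calibration and streams,
full 16-channel montage, effect ramp 0.1 → 1.0), which recovers the
expected sign structure — discriminancy up with run index, race time
down, accuracy up, discriminancy negatively correlated with race time —
with p < .05 in at least 19 of 20 seeded repetitions.

## 8. Statistics

Trend tests are Pearson correlations with two-sided p-values from the
Student-t transform on n − 2 degrees of freedom; the first-vs-last-four
session contrast pools runs per session window and uses the unpaired
two-sided Wilcoxon rank-sum test, exact for small untied samples and
normal-approximated with tie correction otherwise (ties cannot be
enumerated exactly, and midranks with correction are the standard
fallback). Overall command accuracy is the arithmetic mean of the three
per-command true-positive rates; the white-pad true-negative rate is
reported separately and never folded into the mean. All six white pads
(four middle plus start and finish) count toward the true-negative
rate.

## 9. Known limitations

* The generator's independence assumptions (channels, bins, artifacts
  vs state) are idealizations; real SMR data violate all three.
* The Gaussian classifier is deliberately minimal (one prototype per
  class, diagonal covariance); mixture prototypes are representable in
  the model structure but not fit.
* The closed-loop pilot model is a policy on pad types, not a model of
  human reaction time or fatigue; decision latencies therefore reflect
  integrator dynamics only.
* The race simulator covers the single-avatar mechanics; opponents,
  graphics and networking are out of scope.
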