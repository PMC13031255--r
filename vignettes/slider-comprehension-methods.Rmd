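---
title: "Models and methods for continuous comprehension slider data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for continuous comprehension slider data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compslide)
```

# The measurement problem

Speech comprehension is an internal state that fluctuates from moment to
moment, yet it is usually measured after the fact — a rating, a multiple-choice
question, a written summary — so the score confounds comprehension with
memory. A continuous slider lets a listener report comprehension *while*
listening: the device streams 8-bit positions (0–255) every 4 ms (250 Hz),
each reading paired with a device timestamp and a host timestamp.
`compslide` implements the full analysis stack for such data, together with a
synthetic-data generator whose ground truth is known, so every stage can be
validated without hardware.

# Device logs, clock drift, and traces

The device (MCU) clock and the host clock diverge slowly — clock drift. The
host clock is the reference because it is aligned with audio playback, so
`estimate_clock_drift()` fits `device_time = offset + rate_ratio * host_time`
by least squares; `rate_ratio - 1` is the drift fraction (a device running
fast by 400 ppm gives `rate_ratio = 1.0004`), and `to_trace()` maps device
timestamps back to host time with the inverse before resampling. Drift below
0.05% over a trial corresponds to at most ~15 ms at the end of a 30-s trial;
after correction the residual is far below one 4-ms sample period (with USB
jitter enabled in the generator it stays bounded by the ±2 ms jitter itself).

Resampling uses **zero-order hold** by default: the slider reports a held
physical position, not samples of a band-limited signal, so the last reported
value persists until the next report. Linear interpolation is available as an
option. Normalization divides by 255 (the device maximum) so a participant
who never reaches the top is not inflated; per-trial min–max scaling is an
option for visualization-style normalization. Gaps longer than five sample
periods are filled by the hold and counted in the trace's quality metadata.
Sample counts use half-up rounding — a 14.55-s trial at 250 Hz has
3637.5 → 3638 samples — and products such as `5.81 * 250` are snapped at
1e-6 before rounding because binary floating point lands them just below the
exact decimal half.

Trial-level summaries: the **median** of the trace is the single
comprehension score per trial; `crop_initial_movement()` removes the opening
sweep away from the 0 origin with per-rate cutoffs (5, 4, 2.5, 2, 1.5 s for
rates x1–x5, overridable); `pentile_trace_scores()` gives the five
contiguous-bin medians used for time-course analyses; and
`movement_outlier_check()` implements the attention check — each
participant's mean total absolute displacement per trial must lie within 3.5
group standard deviations of the mean. The displacement statistic itself is a
package choice: total absolute first differences, averaged within
participant.

# Scoring written summaries

Three similarity measures compare a written summary against the heard
segment text:

* **Written-summary score** — for each summary word, the maximum cosine to
  any segment word, summed over summary words. Unbounded above, sensitive to
  summary length; a single verbatim match cannot dominate.
* **Heard-segment score** — for each segment word, the maximum cosine to any
  summary word, averaged. Bounded in [−1, 1]; measures coverage of the
  segment and is invariant to duplicated summary words (the written score is
  additive — this asymmetry is intentional and tested).
* **Contextual score** — cosine between single-vector encodings of the two
  texts from a deterministic sentence encoder.

Out-of-vocabulary words are skipped and counted, never replaced by zero
vectors, because a zero vector has no direction and corrupts max-cosine
scores. Stop words are retained (no stop list is assumed); a filter can be
layered on by the caller. Pentile similarity profiles split the *segment
words* into five contiguous bins (by word count, remainder to the earliest
bins) and score the summary against each bin; a profile rising toward bin 5
is a recency signature. Pretrained embedding weights are outside the package:
real tables load from word2vec text format via `read_word2vec()`, and
`make_toy_embeddings()` provides deterministic unit-norm Gaussian vectors
whose cosine geometry behaves like a real table for tests. Because embedding
dimension, casing rules and encoder checkpoints vary between distributions,
results that depend on specific pretrained weights are not reproduced here.

# The comprehension decline: linear versus sigmoid

Median slider scores `y` against speech rate `x` are fit by two models:

$$y = \beta_0 + \beta_1 x
  \qquad\text{and}\qquad
  y = \frac{\beta_0}{1 + e^{-\beta_1 (x - \beta_2)}}$$

In the sigmoid, $\beta_0$ is the maximum asymptote, $\beta_1$ the growth rate
(negative for a declining curve — the sign convention is fixed so recovered
signs are comparable), and $\beta_2$ the center where the main drop occurs.
The sigmoid is fit by bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), initialized at `b0 = max(y)`, `b1 = -1`,
`b2 = median(x)` with `b0` bounded in (0, 1.5] and `b2` within the observed
rates; on non-convergence, ten seeded random restarts are drawn within the
bounds before an error carrying diagnostics is raised.

Model comparison uses 5-fold cross-validation **stratified over speech
rates**: each fold receives an equal number of trials of each rate
(remainder round-robin, shuffled by seed), both models are fit on the
training folds, and the Pearson correlation between predicted and observed
held-out scores is recorded per fold. Per-subject mean correlations are
compared with a Wilcoxon signed-rank test (exact distribution for n ≤ 25,
zero differences dropped). The correlation-based Wilcoxon is the operative
criterion for declaring a winner; cross-validated MSE is reported alongside
but not used for selection. Mixed-effects analyses (random intercepts for
digit span and digit-in-noise) are deliberately delegated:
`build_trial_table()` emits the long-format 0–1-rescaled analysis table and
the formula is documented there, but fitting is routine statistics left to
`lme4` or similar.

# Temporal response functions

The slider trace is modeled as a time-lagged linear function of six stimulus
annotation channels: low- and high-surprisal passage onsets (impulses at the
first word of each passage), word-by-word surprisal (each word's surprisal at
its onset sample; collisions are summed with a warning), segment onset, and
one speech-rate onset channel per rate (x1, x2.5), each an impulse at sample
one of the story. The kernel window is −0.2 to +5 s (at 250 Hz that is 1301
lags per feature and 7806 design columns; analyses in this package's tests
run at 20 Hz, giving 105 lags and 630 columns). Negative lags are retained
as an artifact-detection band: a genuine response cannot precede its
stimulus, so coefficient mass before lag 0 flags leakage.

Estimation is standard ridge regression with $\alpha = 1$ and an unpenalized
intercept. Two numerical points matter:

* **Column centering.** The annotation channels have nonzero means (impulse
  densities), so the design columns are centered along with the response;
  otherwise the sustained part of the dense word-surprisal contribution is
  inexpressible and leaks flat pedestals into the story-start kernels.
* **Story-blocked lagging.** The lagged design is built per story (each
  story zero-padded at its own edges), so lags never bleed across story
  boundaries; responses are causal within a story.

Cross-validation uses contiguous story-blocked folds — shuffled samples would
leak through the strong autocorrelation of the trace — with k = 3 and an
automatic fallback to k = 2 when a fold lacks variation, operationalized as
a constant held-out trace or a constant annotation channel in a training
block. Accuracy is Spearman's ρ (average ranks) between predicted and
observed held-out signals; the reported kernel is refit on all data.
`kernel_peak_latency()` reads a participant's response delay off a feature's
kernel as the lag of the maximum absolute coefficient in [0, tmax]
(earlier lag on ties; an all-zero kernel is an error). The surprisal
ablation refits after removing the three surprisal features and tests the
per-subject drop in ρ with a one-sample t-test; the full and reduced models
share folds and Gram blocks, so the reduced model is an exact column-subset
solve.

# The synthetic-data generator

Every stage is driven by participant profiles with known ground truth:
a declining comprehension sigmoid
(`comp_max / (1 + exp(comp_slope (x - comp_center)))`, defaults drawn from
`comp_max` ∈ [0.75, 1], `comp_slope` ∈ [1.5, 2.5], `comp_center` ∈
[2.5, 3.5] — curves that are high at x1 and near floor at x5); a gamma
delay kernel (shape ∈ [2, 4], scale ∈ [0.3, 0.6] s, i.e. response delays
around 0.5–2 s, unimodal and strictly positive-lag — the family itself is a
modeling choice, as only delayed, smooth responses are observed); motor
noise (SD 0.05 in normalized units); and a linear clock-rate offset up to
500 ppm, with optional i.i.d. ±2 ms USB jitter on host timestamps.
Simulated trials start at the device origin 0 and approach the latent level
through convolution with the delay kernel, are perturbed by motor noise,
clipped to [0, 1], and quantized to 0–255. With zero noise and drift,
preprocessing recovers the latent trace within 1/255 plus hold error — the
round-trip identity the IO tests assert.

Session plans mirror the three designs: 125 short segments (25 per rate,
mean durations 29/14.55/10.93/7.28/5.81 s), 10-minute blocks of 7.5-s
chunks (16 per rate per block, no immediate rate repeats), and four stories
presented at both x1 and x2.5 with ~30-word alternating low/high-surprisal
parts (per-word surprisal Normal(4.91 or 5.90, 0.5) truncated at zero).
Post hoc scores are generated as `round(10 * median latent)` for the rating
and `P(correct) = 0.25 + 0.75 * latent` for the multiple choice — encoding
a guessing floor of 25%; the linear mapping of the rating onto latent
comprehension is a generator choice, not an empirical claim. Written
summaries sample `ceiling(comprehension * n)` segment words without
replacement with inclusion weights `1 + recency_bias * pentile`, so a
positive bias over-represents final fifths.

Word events use a mean inter-word interval of `60 / (195.76 * rate)` s (the
x1 words-per-minute rate) with multiplicative uniform 0.7–1.3 jitter, and
stories open with a variable 0.8–2.5 s narration lead-in. Both choices are
realism *and* identifiability: strictly periodic onsets form an impulse comb
whose spectral nulls leave lagged kernels unidentified, and a constant
lead-in would make the first chunk onset a fixed-shift copy of the segment
impulse. One identifiability constraint is structural and unavoidable: the
segment-onset channel is by definition the sum of the two rate-onset
channels, so only the summed story-start responses are identified and a
ridge estimator converges to the minimum-norm representative. The TRF
generator therefore uses story-start weights satisfying
`w_segment = w_rate_x1 + w_rate_x2p5`, the minimum-norm member, making the
per-feature ground truth the one an unbiased estimator approaches.

## What the generator does not emulate

No audio is synthesized and no forced alignment or language model is run —
word events and surprisal values are generated directly, as those artifacts
are inputs to this package in practice. Real slider data additionally
contain deliberate strategy shifts, hand-switching effects, fatigue drifts
and non-Gaussian motor noise that the generator does not model; passing
tests demonstrate that the estimators recover what the generative model
encodes, not that real data satisfy that model.

# Problem sizes and runtime choices

Cohort-scale studies of the rate models use the score-level generator path
(`simulate_median_scores()`), since only per-trial medians enter those
analyses. TRF studies run at 20 Hz with eight stories of 45 s (75 s for the
ablation study, whose extra-column effects need longer records) — small
enough that a kernel-recovery study over 20 participants and a two-arm
ablation study over 25 participants complete in a few minutes on one CPU,
while preserving the −0.2…+5 s window and α = 1. The full-rate 250 Hz path
is exercised by the device-level tests (sample counts, drift, round-trip).

# A calibration caveat for Spearman-scored ablation

One acceptance property deliberately fails, and the failure is informative.
Under a null generator (surprisal features carry no signal but the other
channels do), dropping the surprisal features *increases* measured ρ by
~0.15–0.2. The mechanism is a rank-tie artifact, not overfitting in the
usual sense: away from story onsets the reduced model predicts a constant,
and average-rank Spearman treats those ties as abstention, while the full
model's noise-fitted surprisal kernels commit to random ranks in the same
spans. Because de-tying ranks does not depend on the wiggles' amplitude, the
effect is invariant to record length, SNR and ridge strength (verified
empirically in all three directions), so |mean Δρ| cannot be brought under
0.05 under these conditions. The artifact is conservative — it can only
*depress* the measured surprisal contribution, never fabricate one — but it
means Spearman-scored ablations on sparse-signal behavioral traces
systematically understate Δρ, a point worth bearing in mind when comparing
ablation magnitudes across studies.

# Worked example

```{r example, eval = FALSE}
library(compslide)

profile <- make_participant(1)
plan <- session_plan("exp1")
records <- simulate_session(plan, profile, fs = 50)
table <- build_trial_table(records)

cmp <- crossval_compare(
  data.frame(x = table$speech_rate, y = table$median_slider_score),
  k = 5, seed = 1)
print(cmp)

fit <- fit_sigmoid(table$speech_rate, table$median_slider_score)
coef(fit)        # compare against profile$comp_max, -comp_slope, comp_center
plot(fit)
```
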