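---
title: "Texture-based eye-movement biometrics: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based eye-movement biometrics: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gazetex)
```

## The recognition model

`gazetex` treats a gaze trajectory as an image and asks whether its
*texture* identifies the person who produced it. The processing chain is

gaze samples → trajectory image → Gabor texture features → probes →
LDA → one-against-one SVMs → DET/EER and CMC/Rank-k.

**Rendering.** The full 1920×1080 screen is mapped anisotropically onto an
N×N canvas (x scaled by N/1920, y by N/1080), because the method's images
are square while the stimulus is widescreen and no letterboxing rule is
assumed; this preserves the whole stimulus area. Consecutive valid samples
are joined by integer (Bresenham) 1-px lines — no anti-aliasing, so
rendering is exactly reproducible and testable against a line-rasterization
oracle. Each traversal adds 0.25 to every pixel on the line, clipped at 1;
the increment gives multi-level gray (slow passages and retraces brighten)
while keeping intensities bounded. Gaps at invalid samples are *not*
bridged, and off-screen samples are clipped. All of these are `render.*`
knobs, so alternatives can be swept.

**Gabor bank.** The complex kernel is a Gaussian envelope modulating a
plane wave; we use σ = 1/f, γ = 1, η = 2, φ = 0, truncated at half-width
⌈3σ⌉ and applied by zero-padded FFT convolution (σ reaches 64 px at the
lowest frequency, so frequency-domain filtering with explicit padding is
the only way to avoid wrap-around; the compiled backend batches images so
kernel FFTs are computed once). The frequency ladder is
f_i = 0.5/(√2)^(i−1): eleven half-octave scales ending exactly at
1/64 = 4/256 cycles/px, the standard "important components" bound f ≥ 4/N
for the largest supported image (N = 256). Two envelope conventions exist
in the literature; the default `variant = "as-printed"` places η only in
the amplitude prefactor and γ only in the exponent, while
`variant = "standard"` uses the conventional (f²/γ²)x′² + (f²/η²)y′² form.
Features are the mean and the *population* standard deviation of each
magnitude response (a fixed convention; at N² pixels the sample/population
distinction is negligible). Features are emitted raw; standardization
happens inside the reduction step so the training set alone defines the
scaling.

**Probes and reduction.** A probe averages `NoET` feature vectors of one
subject, sampled without replacement *within* the probe (probes may overlap
— with 20 training probes of 16 vectors from a ~38-vector pool, strict
global non-replacement is impossible, so within-probe-only non-replacement
is the default and the strict variant a config option). The LDA target
dimension is re-estimated per dataset from the Levina–Bickel
maximum-likelihood intrinsic-dimension estimator (averaged over
neighbourhood sizes 6–12) and capped at k−1; a fixed published value would
be dataset-specific. LDA itself is solved as the generalized eigenproblem
of between- versus within-class scatter with the within scatter always
shrunk by 1e-3·tr(Sw)/p·I: with 176 collinear texture features and a few
hundred training probes the unregularized problem is ill-posed, and the
shrinkage solver is both the numerically safe and the better-performing
choice (an unregularized reference LDA agrees with it on well-conditioned
data; that agreement is a unit test).

**Matching.** One-against-one linear SVMs with C = 1: after LDA the space
is low-dimensional and near-linearly separable, so a linear kernel is the
parsimonious default (RBF with tuned (C, γ) remains available).
Verification scores are the *mean signed margin* of the claimed subject's
k−1 classifiers — a continuous generalization of vote counting that gives
DET curves fine-grained thresholds; plain vote fractions are retained
(`score = "votes"`). Identification ranks subjects by total pairwise votes
with summed margins and then subject label as documented deterministic
tie-breaks.

**Evaluation.** FPR(t) counts impostors at or above the threshold, FNR(t)
genuine scores below it; the EER interpolates linearly between the two
bracketing thresholds where FPR − FNR changes sign (ties grouped at one
threshold). The CMC uses the optimistic tie policy (rank = 1 + number of
strictly greater scores) by default, with the pessimistic variant
available. Score fusion tanh-normalizes each matcher,
s′ = tanh(0.01(s−μ)/σ) + 1, with μ and σ estimated from that matcher's
*training-phase* score pool — estimating them on test scores would leak —
then sums. Headline experiments average over 10 random partitions.

## The synthetic cohort: what it emulates and what it does not

No public dataset accompanies the task, so the package ships a simulator
that emulates the study conditions: a 300 Hz binocular-averaged tracker, a
23-inch 1920×1080 screen at 600 mm, and number-search questions (7-digit
target, right-aligned comparison numbers of lengths 2–5, five answer
options) whose correct answer is the longest matching suffix. Sessions
follow the study bookkeeping — the full replica plan (58 subjects × 2
trials × 4 tests × 40 questions = 18,560 recordings) is checked at the
plan level, while simulated experiments run a desk-scale default of 10
subjects × 54 questions (540 recordings), large enough for 70/30 splits at
NoET = 16 and small enough to evaluate in minutes on one CPU.

Per-subject **oculomotor profiles** drive the gaze model: Gamma fixation
durations (population mean 250 ms), a linear amplitude–duration main
sequence (21 ms + 2.2 ms/deg) with minimum-jerk saccade velocity profiles,
Ornstein–Uhlenbeck within-fixation drift plus Gaussian tremor, a saccadic
landing gain (habitual slight undershoot, population 0.95), a biased
region-visit order, and a target-revisit probability. The `separation`
knob scales all between-subject spreads; 0 collapses the cohort to
identical profiles. The spreads deliberately put most idiosyncrasy into
*where* the gaze goes (scan preferences, revisits, landing gain) and keep
gross temporal scales mildly subject-specific, with question-to-question
jitter of the strategy parameters (attentional state noise): a generator
whose subjects differed mainly in how *much* trace they draw would be
identifiable from the two gray-level summary statistics alone, which
contradicts the documented near-uselessness of those controls on real
data. Trial-2 recordings come from profiles jittered multiplicatively
(`aging_sd`), reproducing qualitative template aging without claiming its
magnitudes.

What the simulator does **not** model: blinks and tracker artifacts beyond
a uniform dropout probability, pupil dynamics, cognitive search strategy
beyond biased orders and revisits, calibration drift, and the actual
difficulty of reading digits. Passing tests on synthetic cohorts therefore
demonstrates that the pipeline recovers identity signal of the kinds the
generator encodes — not that it reaches any particular accuracy on real
recordings.

## Numerical choices and degenerate inputs

* Sub-seeds for every randomized stage derive deterministically from one
  global seed, so pipelines are bit-reproducible.
* Kernel truncation at ⌈3σ⌉; FFT sizes are the next power of two covering
  the full linear convolution.
* Downsampling is pure decimation (every k-th sample, first kept): the
  conservative reading of deriving a slower tracker from a faster one; an
  averaging variant would low-pass filter and is intentionally not the
  default.
* I-VT: 30 deg/s threshold, 60 ms minimum fixation (community defaults;
  the method itself prescribes no detector). Central finite differences
  for velocity, one-sided at the ends; too-short fixation runs are
  relabelled as saccade samples and merged, so events partition the valid
  samples.
* GMM-UBM: diagonal covariances, k-means initialization (seeded), variance
  floor 1e-8; mean-only MAP adaptation. Degenerate inputs (point masses,
  duplicate rows in the intrinsic-dimension estimator) are floored or
  jittered with warnings rather than failing.
* EER on degenerate single-sided crossings falls back to the threshold
  minimizing |FPR − FNR|.
* The published benchmark table bundled in `reference_gwt_results()` is an
  *input* for report arithmetic (relative losses between short-term and
  long-term results); the synthetic pipeline does not attempt to reproduce
  those absolute numbers, which belong to a private 58-subject dataset.

## Known limitations

* The five-option answer row uses labels 1–5 with the correct answer
  always in 2–5 (answer lengths span 2–5; guessing succeeds at 1/5). The
  task description leaves the fifth question kind unspecified; the layout
  generator exposes four kinds.
* The CEM baseline is classified through the same LDA+SVM pipeline as the
  texture features rather than its original weighted-comparison scheme, to
  isolate feature quality under one classifier; it is flagged
  "simplified".
* The LVD baseline's window length maps to one second of samples (hop a
  tenth of that), capped per recording; its original formulation ties the
  window to the probe size more loosely.
* Verification-score matrices drive the DET; identification uses vote
  totals. Fusing matchers fuses the continuous (margin) matrices.
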