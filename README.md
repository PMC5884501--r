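# gazetex

Eye-movement biometrics from the *texture* of gaze trajectories.

People differ in how they move their eyes: fixation durations, saccade
kinematics (the amplitude–duration "main sequence"), landing accuracy and
habitual scanning strategy all reflect an individual's oculomotor plant and
neurocognitive control. `gazetex` implements a recognition method that
exploits this: raw gaze recordings from a visual number-search task are
rendered as square grayscale **trajectory images**, a multi-scale **Gabor
wavelet bank** turns each image into a texture descriptor, and subjects are
verified/identified with **LDA + one-against-one SVMs**. The package is
aimed at researchers in behavioral biometrics and eye-movement analysis who
want a tested, fully reproducible implementation that runs end to end on a
bundled synthetic scanpath simulator (no human data required).

## The method

For a gaze recording `(GazePointX(t), GazePointY(t))` in screen pixels:

1. **Render** the trajectory onto an N×N canvas (N = 64/128/256; "pixET"),
   connecting consecutive valid samples with 1-px lines whose intensity
   accumulates per traversal (clipped at 1).
2. **Texture features.** Each image is convolved with a bank of complex
   Gabor wavelets

   `G(x,y) = f²/(πγη) · exp(−(x′² + γ²y′²)/(2σ²)) · exp(i(2πf x′ + φ))`

   with σ = 1/f, γ = 1, η = 2, φ = 0, on a half-octave frequency ladder
   `f_i = 0.5/(√2)^(i−1)`, i = 1…11 (down to 1/64 = 4/256 cycles/px, the
   classical `f ≥ 4/N` design bound at N = 256) crossed with 8 orientations
   `θ_j = π(j−1)/8` — 88 kernels. The mean and standard deviation of each
   magnitude response give a **176-dimensional feature vector**.
3. **Probes.** A probe is the mean of `NoET` feature vectors of one subject
   (NoET ∈ {2, 4, 8, 16}); averaging shrinks within-subject variance like
   `Var(X̄) = σ²/n`.
4. **Matching.** Features are standardized, reduced by LDA (target
   dimension from a maximum-likelihood intrinsic-dimension estimate, capped
   at k−1), and matched with k(k−1)/2 pairwise linear SVMs. Verification
   scores are signed margins of the claimed subject's k−1 classifiers;
   identification ranks subjects by pairwise votes.
5. **Evaluation.** DET curves / EER for verification, CMC / Rank-k
   identification rates for identification; `tanh` score normalization
   `s′ = tanh(0.01(s−μ)/σ) + 1` and sum-rule fusion combine matchers.

Baseline matchers (LVD direction histograms with GMM-UBM scoring, fixation
density maps, CEM fixation/saccade statistics over I-VT events) and
template-aging / temporal / spatial robustness experiment drivers are
included for comparison studies.

## Worked example

```r
library(gazetex)
geom <- screen_geometry()                      # 23" 1920x1080 at 600 mm

# simulate a 10-subject cohort answering 54 number-search questions
sess <- simulate_session(session_plan(10, 1, 1, 54, seed = 7), geom,
                         separation = 1)

# texture features (540 images rendered at 128 px, 176 features each)
gwt <- gwt_dataset(sess$recordings, geom)

# probe-size sweep, short-term split, averaged over partitions
run_noet_sweep(gwt, NoET_grid = c(2, 4, 8, 16), split = "ST",
               n_partitions = 5, seed = 5)
```

```
  NoET        eer     rank1
1    2 0.17074074 0.6333333
2    4 0.12814815 0.7233333
3    8 0.10925926 0.8666667
4   16 0.08888889 0.9000000
```

Reading: with 16 trajectories averaged per probe the verification EER of
the texture matcher on this synthetic cohort is ≈ 8.9% and 90% of test
probes are identified at rank 1 (chance = 10%); both improve monotonically
with the probe size, as the `σ²/n` argument predicts. The 2-dimensional
gray-level control features (`gi_dataset`) stay far behind on the same
recordings, showing that the texture — not the gross amount of trace —
carries the identity signal.

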