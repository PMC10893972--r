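---
title: "Decoding orientation working memory with periodic SVR: models and methods"
author: "psvrmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding orientation working memory with periodic SVR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psvrmem)
```

## The scientific problem

In a delayed-estimation working-memory task, an observer memorizes the
orientation of a grating across a retention delay and then reproduces it by
rotating a probe. Orientation is a circular feature with period 180°: a
grating at θ and at θ + 180° is physically identical. Two linked questions
drive the analyses in this package: (i) can the memorized orientation be
read out, time-resolved, from multivoxel fMRI patterns in early visual
cortex during the delay, and (ii) how does the fidelity of that neural
readout relate to behavioural precision? Because raw scanner data are
rarely shareable, every stage here is paired with a generative simulator so
the whole pipeline is verifiable end to end on synthetic data.

## The trial design

Each run presents 40 trials. Targets are the 40 equally spaced orientations
`1.125° + k · 4.5°` (k = 0..39), i.e. 1.125°–176.625°: the 4.5° spacing
tiles the 180° space, and the global 1.125° shift keeps every stimulus off
the exact cardinal axes (0°, 45°, 90°, 135°), where perceptual anisotropies
would otherwise concentrate. Distractors are the same grid shifted by half
a step (2.25°), so the two sets never collide and also avoid cardinals.
Within a run each target and each distractor appears exactly once, in
independently randomized order; a retro-cue (1 or 2) marks which serial
position is the target. Eight runs give 320 trials per subject.

`generateDesign()` constructs exactly this table; with
`orientations = "continuous"` it instead draws targets uniformly on
[0°, 180°), the convention of the pure simulation study.

## The voxel simulator

A voxel's idealized orientation tuning profile is a smooth random periodic
function: a draw `z ~ N(0, K)` over a grid of p points `x ∈ [0, 2π)`, with
the exp-sine-squared covariance

```
K(x_m, x_n; σ) = exp( −2 sin²((x_m − x_n)/2) / σ² )
```

which is the standard periodic kernel: unit variance at zero lag,
2π-periodic, with smoothness set by σ. Each voxel receives its own
smoothness `σ_i ~ Γ(shape = 2, scale = 2)` (mean 4). The gamma
parameterization is stated explicitly because shape/rate and shape/scale
conventions collide in the wild; `sampleTuningProfiles()` exposes both
`shape` and `scale` as arguments. A diagonal jitter of 1e-6 is added before
the Cholesky factorization; the kernel itself is positive semidefinite, the
jitter only absorbs floating-point round-off.

The measured signal of voxel i on trial j is

```
y_ij = z_i(θ_j) · s + ε_ij,    ε_ij ~ N(0, 1) i.i.d.
```

with s ∈ [0, 1] a signal-to-noise scaling factor; s = 0 is pure noise. The
trial orientation θ ∈ [0, 180°) is mapped to the tuning grid as
2πθ/180 and snapped to the nearest grid point; the default grid size of
p = 180 keeps the quantization at or below 1°. (The grid size of the
original simulation is not recorded anywhere we could consult, so 180 is
this package's choice, made for its quantization bound, not an inference
about the original.) Noise is independent across trials, voxels and runs;
hemodynamic convolution, physiological noise and spatial voxel
correlations are deliberately out of scope — the simulator exists to
validate the decoding and inference machinery, not to imitate scanner
physics. Consequently, passing tests demonstrate correctness of the
pipeline's logic and calibration under ideal noise, and say nothing about,
e.g., robustness to temporally autocorrelated noise.

`expandToTimecourse()` turns the trialwise simulation into a TR-resolved
series by placing each trial's pattern into a chosen window of TRs
("active" TRs, standing in for the delay period) and filling the rest with
fresh unit noise. This is plumbing the time-resolved decoder needs for
testing; the per-TR replication of one pattern is not a hemodynamic model.

## Behavioural model (von Mises mixture)

A report θ_r given target θ_t and distractor θ_d follows a three-component
mixture: with probability r1 the observer detects the target (von Mises
error around θ_t), with r2 they swap (von Mises around θ_d), with r3 they
guess (uniform error on [−90°, +90°)):

```
P(θ_r | θ_t, θ_d) = r1 · exp(κ1 cos(Δ_t − μ̃)) / (2π I0(κ1))
                  + r2 · exp(κ2 cos(Δ_d − μ̃)) / (2π I0(κ2))
                  + r3 / (2π)
```

where `Δ = circDiff180(θ_center, θ_r) · π/90` maps the signed circular
difference (±90°) onto the full circle (±π) — the doubled-angle scale on
which the von Mises is the natural circular error law — and the bias μ
(stored in degrees) is scaled identically (μ̃ = μπ/90) and shared by both
von Mises terms. The density is taken with respect to the doubled-angle
radian measure and integrates to 1 over one period (verified numerically
in the tests). κ1, the precision of detections, is the behavioural
precision measure of interest.

Numerics: Bessel normalizers are evaluated with exponential scaling
(`besselI(κ, 0, expon.scaled = TRUE)`), so the density is stable for
arbitrarily large precisions; the parameter container accepts κ up to 1e6,
which covers degenerate error-free simulations. Log-densities are floored
at 1e-300.

**Fitting.** No estimation algorithm is canonical for this model, so the
package makes its own choice: maximize the log-likelihood with BFGS on an
unconstrained reparameterization — softmax for (r1, r2, r3), log for the
precisions, 90·tanh for the bias — from 10 start points (one moment-based,
the rest random), keeping the best. The precision search is capped at
κ = 700 and fits at that bound are flagged as boundary fits rather than
trusted, since they indicate (numerically) error-free data. One genuine
non-identifiability needs a convention: a von Mises component with κ ≈ 0
is exactly the uniform distribution, so on guess-heavy data the
likelihood is flat along the ridge that trades r2 (at κ2 ≈ 0) against
r3. Fits therefore canonicalize any component with κ̂ ≤ 0.1 into the
guess component — 0.1 is well above the O(1/√n) precision a von Mises
fits to pure noise, and far below any behaviourally meaningful
precision. Recovery
performance under the study conditions (320 trials, r1 ∈ [0.85, 0.98],
κ1 ∈ [3, 9]) is exercised in the acceptance tests: median errors below 1.0
in κ1 and 0.04 in r1.

## Preprocessing

**Cubic-spline detrending** (`splineDetrend`). Slow scanner drifts are
modelled per voxel and run by averaging the run into nTrials/2 equal
segments (20 nodes for a 40-trial run), placing a node at each segment
centre, interpolating a natural cubic spline through the nodes, and
subtracting it. The node count is deliberately half the trial count so the
drift model is too coarse to absorb within-trial stimulus-locked structure
(verified in the tests: a trial-locked oscillation survives detrending with
correlation > 0.95 while a linear drift is removed to machine precision).
An odd trial count has no defined node rule and raises an error directing
the caller to set `nNodes` explicitly. Node abscissae sit at segment
centres — an unbiased local level estimate.

**Temporal smoothing** (`temporalSmooth`). A centred moving average of
width 3 TR; at the run edges the window shrinks to the available
neighbours, preserving length without padding artifacts.

**Feature-space smoothing** (`featureSpaceSmooth`). Trials with nearby
orientations evoke similar patterns, so a Gaussian kernel over circular
orientation distance (period 180°, σ = FWHM/√(8 ln 2), weights normalized
to 1) averages each trial's pattern with its feature-space neighbours,
suppressing noise without adding information: at s = 0 the pipeline still
decodes at chance (the null-calibration acceptance test), while at
moderate SNR smoothing raises accuracy. Two scope decisions: the kernel is
keyed on each trial's *target* orientation, and averaging pools only
trials *within the same run* — pooling across runs would let training-fold
information leak into test folds under leave-one-run-out cross-validation.
Whether the original analysis pooled across runs is not documented; the
leakage-safe choice is the default here and the alternative is reachable
via `scope = "all"` so the difference is measurable.

**Voxel selection** (`selectVoxels`). The pipeline takes precomputed
per-voxel activation scores (in real data, t-scores of a
stimulus-versus-baseline contrast restricted to an anatomical region; ROI
construction itself is out of scope) and keeps the n highest, ties broken
toward the lower index for determinism.

## The periodic SVR decoder

Orientation labels are projected onto two sinusoids of period 180° —
`x = sin(2θπ/180)`, `y = cos(2θπ/180)`, i.e. the 45°-shifted pair — so
that the circular label becomes two real-valued regression targets. Each
component is predicted from the voxel pattern by an independent
ε-insensitive support vector regression with RBF kernel (LIBSVM via
**e1071**), and the angle is recovered with the four-quadrant inverse
tangent `θ̂ = atan2(x̂, ŷ)`, mapped back to [0°, 180°). Predicted pairs are
used as-is, not renormalized to the unit circle. Encode→decode is an exact
round trip (tolerance 1e-9), and decoding is equivariant under label
rotation on a noise-free toy within 1°.

Feature scaling is "across-scaling": per feature, the training fold is
mapped to [0, 1] and the *same* parameters are applied to the test fold
(which may therefore leave [0, 1]); features constant in training map
to 0. Cross-validation is leave-one-run-out: each run is predicted by a
model trained on all other runs, with scaling, smoothing scope and
hyperparameters all confined to the training folds.

Hyperparameters are not documented for the original analysis, so the
package fixes library-conventional defaults and exposes them in
`decoderSpec()`: cost 1, ε-tube 0.1, and RBF γ = 1/(n_features · var of
the training fold). Quantitative results that depend on these values are
treated as qualitative properties (orderings, calibration), not bit-exact
targets.

`reconstructTimecourse()` repeats extract → smooth → decode at each of the
30 TR offsets (24 s at TR = 0.8 s) after delay onset, for any of the four
label kinds (target, distractor, probe start, report).

## Accuracy metrics

**FCA** rescales the absolute circular deviation linearly onto 0–100%:

```
FCA(θ, θ̂) = (90 − |θ − θ̂|_circ) / 90 · 100
```

100% is perfect, 50% corresponds to a 45° deviation — the chance level for
circular orientations — and 0% is orthogonal.

**BFCA** integrates trialwise FCA over the orientation space,
`(1/180) ∫ FCA dθ`, by trapezoidal quadrature across trials sorted by true
orientation. Sparsely sampled label regions get wide trapezoids and hence
more weight; densely sampled regions cannot dominate — the continuous
analogue of balanced accuracy. Two quadrature conventions are this
package's own (how the original handled them is not recorded): FCA values
of trials with *identical* true labels are averaged before integration
(zero-width trapezoids would otherwise make the result order-dependent),
and the integral is closed circularly by re-appending the first sorted
trial at its label + 180°, so one full period is covered and a constant
FCA integrates exactly to itself.

`meanWindowAccuracy()` averages per-TR BFCA over the delay-period window,
by default TRs 6–15 counted 1-based from delay onset (10 TRs ≈ 4 s after
delay onset to 2 s after probe onset): late enough for the ~5 s
hemodynamic buildup, early enough to exclude probe-driven perceptual
signal.

## Hyperparameter optimization and group inference

**Nested across-subject grid search** (`nestedGridAssign`). Smoothing FWHM
(0–90° by 10°) and voxel count (250–2500 by 250) form a 10 × 10 grid. Each
subject is assigned the cell that maximizes mean delay-window accuracy
*across all other subjects* — the subject's own results are never
consulted, so the selection cannot overfit subject-level noise. This
leave-one-subject-out integrity is enforced by a sentinel-poisoning test.
Exact ties go to the smaller FWHM, then the smaller voxel count (less
smoothing and fewer voxels are the more conservative choices).

**Cluster-mass permutation** (`clusterPermutation`). Time-resolved
accuracy is tested against chance with a cluster-based permutation test
that controls family-wise error over the autocorrelated TR axis: per-TR
one-sample t statistics, clusters of contiguous TRs above the one-tailed
cluster-forming threshold (α = .05 on the t distribution, above-chance
direction only), cluster score = t-mass (sum of t values), and a null
distribution of the maximum cluster mass obtained by sign-flipping each
subject's chance-centred timecourse (the standard exchangeability argument
for one-sample designs; the original's exact scheme and threshold are not
documented, so these conventional choices are stated rather than
inferred). p = (1 + #{perm ≥ obs}) / (1 + N), the small-sample-corrected
estimate, so p ≥ 1/(N+1) by construction. TRs with zero variance are
excluded with a warning. Group comparisons use pooled-variance two-sample
t tests and Pearson correlations; Bayesian follow-up tests are out of
scope (the pipeline writes out the per-subject quantities they would
need).

## The orchestrated experiment

`runExperiment()` composes the stages: simulate two groups (voxel
timecourses plus behavioural reports per subject) → detrend and
temporally smooth → evaluate the (FWHM × voxel count) grid → assign
parameters leave-one-subject-out → reconstruct full timecourses at the
assigned parameters → per-group cluster permutation, two-sample
delay-accuracy comparison, and the correlation of delay accuracy with
fitted κ1. All randomness derives from one master seed via per-stage,
per-subject sub-seeds, so the manifest (seed + config + package version)
reproduces every output table bit-identically. At reduced scale the grid
stage decodes the trialwise delay patterns directly (one pseudo-TR): in
this simulator the delay content *is* the trialwise pattern, so the grid
ranking is the same while the cost drops by the TR count; the full
timecourse is still decoded at the assigned parameters.

`runSmoothingSimulation()` maps mean BFCA (with standard error) over an
SNR × FWHM grid. The full-scale study grid is 11 SNR levels (0, 0.1–1) ×
37 FWHM levels (0–360° by 10°) × 1000 repetitions; the package default is
a reduced grid, and the tests use the cells and repetition counts stated
with each test (e.g. 50 repetitions of the s = 0 row at FWHM 0° and 60°,
30 repetitions for the SNR ordering at 250 voxels and 8 runs). These
problem sizes are the package's chosen verification scale: large enough
that the Monte-Carlo standard error of a mean BFCA is a few tenths of a
percent, small enough to run routinely.

The spec of this pipeline is function-level; users drive it from R (or
`Rscript -e`). The exported functions, this vignette and the worked
example in the README are the intended interface; `scripts/acceptance.R`
shows the pattern for scripted use.

## Known limitations

- The simulator omits hemodynamics, temporal autocorrelation and spatial
  voxel correlations; calibration results transfer to real data only to
  the extent those factors respect the leave-one-run-out structure.
- SVR hyperparameters are conventional defaults, not tuned; absolute
  accuracy levels on real data will depend on them.
- The behavioural model assumes a shared bias μ in detection and swap
  components and reports no separate swap/guess split uncertainty.
- Decoding quality at very low trial counts (< 2 runs) is undefined by
  design: leave-one-run-out needs at least two runs.
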