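# psvrmem

Periodic support vector regression decoding of orientation working memory,
with a fully generative test bench.

## What this package is for

In delayed-estimation working-memory experiments, an observer memorizes the
orientation of a grating across a delay and reproduces it by rotating a
probe. Multivariate fMRI analyses ask whether — and when — the memorized
orientation can be read out from voxel patterns in early visual cortex, and
how the fidelity of that readout relates to behavioural precision. This
package implements the full analysis chain for such studies, for
researchers in computational neuroimaging and for methodologists who want
a verifiable reference implementation:

- **Simulator** (`generateDesign`, `sampleTuningProfiles`,
  `simulateVoxelResponses`, `expandToTimecourse`, `simulateBehavior`):
  counterbalanced 40-orientation trial designs; voxel populations with
  smooth periodic tuning drawn from an exp-sine-squared Gaussian-process
  kernel, `K(x_m, x_n; σ) = exp(−2 sin²((x_m − x_n)/2)/σ²)`, with
  per-voxel smoothness σᵢ ~ Γ(2, 2); measured signal
  `y_ij = z_i(θ_j)·s + ε_ij` with SNR factor s and unit Gaussian noise;
  behavioural reports from a detection/swap/guess mixture.
- **Preprocessing** (`splineDetrend`, `temporalSmooth`,
  `featureSpaceSmooth`, `selectVoxels`): cubic-spline drift removal with
  the node count fixed at half the trial count, a width-3 TR moving
  average, circular Gaussian feature-space smoothing (σ = FWHM/√(8 ln 2),
  within-run so cross-validation folds stay independent), and
  activation-score voxel selection.
- **Decoder** (`encodeLabels`, `decodeLabels`, `scaleAcross`, `loroCv`,
  `reconstructTimecourse`): periodic SVR — the 180°-periodic label is
  projected onto x = sin(2θπ/180), y = cos(2θπ/180), each component is
  regressed from the voxel pattern by an ε-insensitive RBF-kernel SVR
  (LIBSVM via e1071), and the angle is recovered as θ̂ = atan2(x̂, ŷ);
  leave-one-run-out cross-validation with train-fold-only [0, 1] scaling.
- **Metrics** (`fca`, `bfca`, `meanWindowAccuracy`): feature-continuous
  accuracy `FCA = (90 − |θ − θ̂|_circ)/90 · 100` (100% perfect, 50%
  chance, 0% orthogonal) and its label-balanced trapezoidal integral
  BFCA = (1/180)∫ FCA dθ.
- **Behavioural model** (`vmmmDensity`, `fitVmmm`): von Mises mixture
  over reports — detection (precision κ₁, shared bias μ), swap (κ₂),
  guess (uniform) — fitted by constrained maximum likelihood with
  multistarts.
- **Inference** (`clusterPermutation`, `groupCompare`, `correlate`,
  `nestedGridAssign`): cluster-mass sign-flip permutation over decoding
  timecourses, pooled-variance group tests, Pearson correlations, and
  leave-one-subject-out selection of smoothing width × voxel count.
- **Orchestration** (`pipelineConfig`, `runExperiment`,
  `runSmoothingSimulation`): the end-to-end simulated experiment and the
  SNR × smoothing accuracy surface, reproducible from one master seed.

See `vignettes/psvrmem-methods.Rmd` for the models, the numerical
conventions and the design decisions.

## Worked example

Simulate a subject at moderate SNR, decode the remembered orientation with
and without feature-space smoothing, and fit the behavioural model:

```r
library(psvrmem)

ds <- simulateVoxelDataset(nRuns = 8, nVoxels = 250, snr = 0.5, seed = 7)
samp <- extractTrialSamples(ds$series, ds$design, 0)

pred0 <- loroCv(samp)                         # leave-one-run-out pSVR
bfca(trialLabels(samp, "target"), pred0)
#> [1] 88.7

sm <- featureSpaceSmooth(samp, 60)            # FWHM 60 degrees
bfca(trialLabels(sm, "target"), loroCv(sm))
#> [1] 96.7

p <- VMMMParams(0.947, 0.028, 0.025, kappa1 = 5.673, mu = -0.889)
beh <- simulateBehavior(ds$design, p, seed = 8)
fittedParams(fitVmmm(beh, seed = 9))
#> von Mises mixture parameters
#>   r = (0.971, 0.000, 0.029)  kappa = (5.115, 4.358)  mu = -1.638 deg
```

Reading the numbers: 88.7% balanced accuracy means the decoder's
reconstructions deviate from the true orientations by ~10° on average
(50% would be chance, i.e. 45° deviations); smoothing trials with
neighbouring orientations raises accuracy to 96.7% because it suppresses
noise shared across the feature space without adding information (at
snr = 0 the same pipeline stays at 50%). The mixture fit recovers the
generating behavioural parameters from 320 trials: detection rate
r₁ ≈ 0.97 (truth 0.947), precision κ₁ ≈ 5.1 (truth 5.673), bias within
sampling error of the truth; swap and guess components are weakly
identified at this trial count, as expected.

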