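# Shared fixture builders; all synthetic, generated at test time.

# noise-free decoding toy: features are exactly the encoded sinusoid pair,
# labels balanced over the 40-level grid, nRuns runs
makeNoiseFreeToy <- function(nRuns = 4L) {
  theta <- rep(1.125 + 4.5 * (0:39), nRuns)
  list(theta = theta, X = encodeLabels(theta),
       runs = rep(seq_len(nRuns), each = 40L))
}

# small trialwise dataset + extracted samples in one call
makeDecodableSamples <- function(nRuns = 4L, nVoxels = 80L, snr = 1,
                                 seed = 1L) {
  ds <- simulateVoxelDataset(nRuns = nRuns, nVoxels = nVoxels, snr = snr,
                             seed = seed)
  list(design = ds$design, series = ds$series,
       samples = extractTrialSamples(ds$series, ds$design, 0L))
}

# behavioural dataset from known truth
makeBehavior <- function(r1 = 0.947, r2 = 0.028, r3 = 0.025,
                         kappa1 = 5.673, kappa2 = 5.673, mu = -0.889,
                         nRuns = 8L, seed = 1L) {
  p <- VMMMParams(r1, r2, r3, kappa1 = kappa1, kappa2 = kappa2, mu = mu)
  d <- generateDesign(nRuns, seed = seed)
  list(truth = p, data = simulateBehavior(d, p, seed = seed + 1L))
}
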