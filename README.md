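# neuroddm

Linking single-trial EEG evidence to the dynamics of rapid perceptual
decisions.

## The scientific problem

In speeded two-alternative categorisation tasks (face vs car images,
presented alone, V, or with congruent sounds, AV), multivariate decoding of
the EEG reveals two temporally distinct neural representations of the
decision evidence: an **Early** sensory component (~180–360 ms after
stimulus onset) and a **Late** post-sensory component (~400–600 ms) whose
single-trial amplitude indexes the quality of the evidence entering the
decision. The question this toolchain addresses is *where* a multisensory
behavioural benefit arises: in early sensory encoding, or in the
post-sensory decision evidence — and it answers it by feeding the
single-trial EEG amplitudes into a hierarchical drift-diffusion model
(DDM) of the behaviour.

`neuroddm` implements that full analysis chain for researchers in
cognitive/computational neuroscience, plus a synthetic-data generator so
that every stage is testable end to end without any recordings:

1. **Sliding-window decoding** (`looAz`): a spatial weighting `w` is
   learned per 60 ms window by penalized logistic regression, giving the
   one-dimensional projection `y = w'x` of the multichannel signal `x`
   (face trials map to positive, car trials to negative `y`). Performance
   is the ROC area `Az` of leave-one-trial-out amplitudes; significance
   comes from label-permutation nulls (`permutationThreshold`); scalp
   couplings from the forward model `a = X y / (y'y)` (`forwardModel`).
2. **Component identification** (`clusterTopographies`,
   `defineComponentWindows`): k-means clustering of the per-window forward
   models (silhouette-selected k) locates the Early→Late transition; a
   40 ms guard gap centred on it defines the component windows.
3. **Group statistics** (`bootstrapAzDifference`, `minClusterSizeNull`):
   a percentile bootstrap of the per-sample median AV−V Az difference,
   thresholded by a data-driven minimum cluster size from a
   temporal-shuffling null; robust percentage-bend correlations and
   ex-Gaussian mixture tests of RT bimodality.
4. **Neurally informed hierarchical DDM** (`samplePosterior`): the trial
   drift rate is regressed on the component amplitudes,

   `delta = gamma0 + gamma1 * yEarly + gamma2 * yLate * C`,

   with C the stimulus phase coherence, participant parameters
   (`gamma`s, boundary separation `alpha`, starting point `beta`,
   nondecision time `nDT`, per condition) nested in group-level Gaussians.
   Inference is by adaptive Metropolis-within-Gibbs MCMC on an exact
   Wiener first-passage-time likelihood (`wienerFPTDensity`), with
   Gelman–Rubin convergence checks (`gelmanRubin`) and DIC model
   comparison (`dic`) across the regression variants
   (`scale_late`, `scale_early`, `scale_both`, `early_on_ndt`,
   `behavior_only`).
5. **Synthetic studies** (`makeSyntheticTruth`, `generateSessionDesign`,
   `simulateDDMDataset`, `synthesizeEEGEpochs`, `applyTrialExclusions`):
   balanced 720-trial sessions (2 modalities × 2 categories × 4 coherence
   levels), DDM-generated choices/RTs, and 64-channel epochs containing
   two rank-one spatiotemporal components whose latent amplitudes are the
   same ones that drove the behaviour — with the generating truth retained
   for recovery tests. `runPipeline` orchestrates all stages with a
   reproducible manifest.

## Worked example

```r
library(neuroddm)

# a small synthetic study: 4 participants, 128 trials, 8 channels
truth <- makeSyntheticTruth(nParticipants = 4, nChannels = 8, seed = 1,
                            noiseSD = 3)
tab <- do.call(rbind, lapply(1:4, function(p) {
    d <- generateSessionDesign(128, 32, seed = p, participant = p)
    simulateDDMDataset(d, truth, seed = 100 + p)
}))

# decode one participant's V trials
ep <- synthesizeEEGEpochs(tab[tab$participant_id == 1, ], truth,
                          fs = 100, epochWindow = c(-0.1, 0.8), seed = 7)
i  <- tab$participant_id == 1
m  <- looAz(ep, tab$category[i] == "face",
            cfg = slidingWindowConfig(range = c(0, 0.7), step = 0.02),
            condition = "V")
m
#> DiscriminantMap [V]: 36 windows (60 ms wide), 128 trials; peak Az = 0.996 at 500 ms

# fit the neurally informed hierarchical DDM (reduced chains for the demo)
fit <- samplePosterior(tab, variant = "scale_late", nChains = 2,
                       nSamples = 400, burnIn = 150, thin = 2, seed = 2)
fit
#> PosteriorSamples [scale_late]: 2 chains x 125 retained draws, 72 parameters
#>   max group-level Rhat = 1.0304
dic(fit)$dic
#> [1] -81.46489
```

The peak decoding near 500 ms is the Late component the generator
injected; the DIC value is the fit/complexity score used to rank the
drift-regression variants (lower is better — compare against
`variant = "behavior_only"` to see the benefit of the neural regressors).

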