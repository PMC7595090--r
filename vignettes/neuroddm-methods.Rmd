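---
title: "Methods: from single-trial EEG decoding to a neurally informed drift-diffusion model"
author: "neuroddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-trial EEG decoding to a neurally informed drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroddm)
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions they make, the tunable parameters that matter,
and the design choices taken where the methodology was genuinely open. It
states no empirical result that the test suite and the acceptance script do
not themselves compute.

## 1. The analysis problem

A participant categorises briefly presented noisy images as faces or cars,
either purely visually (V) or with a congruent sound (AV), under a 1.5 s
response deadline. Visual evidence strength is controlled by the image
phase coherence (four levels, 27.5–35%). Multichannel EEG is recorded;
behaviour is (choice, RT) per trial. The chain implemented here asks: when
and where in the neural timecourse does the multisensory benefit arise,
and which neural representation drives the rate of evidence accumulation?

## 2. Sliding-window linear discrimination

Within each 60 ms window (10 ms onsets; stimulus-locked −100..1000 ms,
response-locked −600..500 ms) a spatial weighting $w$ maximally separates
face from car trials, giving the one-dimensional projection
$y = w^\top x$, with the convention that face trials map to positive $y$.

**Observation handling.** Each time sample inside the window is treated as
an independent observation sharing the same $w$ — the classic single-trial
formulation; the alternative (averaging samples before fitting) discards
the within-window degrees of freedom. This is a design choice, not a
mathematical necessity.

**Estimator.** Penalized logistic regression by IRLS, intercept included
but excluded from the scalp projection. The ridge penalty is trace-scaled,
$\lambda = \texttt{l2} \cdot \mathrm{tr}(X^\top X)/D$ with `l2 = 1e-4` by
default — small enough to leave well-conditioned problems untouched,
large enough to keep 64-channel windows and separable (noiseless) cases
finite. IRLS runs from zero weights, tolerance `1e-8`, at most 500
iterations (non-convergence is an error, not a silent result).

**Validation.** Az is the ROC area of *out-of-sample* amplitudes from
leave-one-trial-out cross-validation, computed by the rank (Mann–Whitney)
statistic with midrank ties. Significance thresholds come from
re-running the full LOO pipeline on label permutations and pooling the
null Az values over windows (default 1000 permutations; at least 100).

**Forward models.** $a = Xy/(y^\top y)$ maps each discriminating
component back to a scalp topography. On exact rank-one data this returns
the generating topography identically; with noise, the correlation with
truth approaches 1 as SNR grows (an acceptance check).

## 3. Early/Late component identification

Within the sustained significant decoding period, per-window forward
models are clustered by seeded k-means (Euclidean metric, 20 restarts);
the number of clusters is selected by mean silhouette. Silhouette cannot
score $k=1$, so a floor is needed to *decide* "one component": if the best
candidate's mean silhouette falls below 0.25 the sequence is declared
single-component. The floor was calibrated once against the two regimes
the decision must separate — unstructured noise around a single topography
(mean silhouette ≈ 0.1–0.2 at 32 channels) versus genuinely two-regime
sequences (≥ 0.3 even at high noise) — and then frozen. Raw labels are
made temporally contiguous by a 3-window majority filter; the transition
is the midpoint between the last window of the first temporal cluster and
the first of the next. A 40 ms guard gap centred on the transition defines
the Early and Late windows (e.g. a 380 ms transition in a 180–600 ms
range yields 180–360 and 400–600 ms).

Participant-specific selection windows: Early at the individual peak Az
across V and AV within the Early range; Late at the individual peak
AV−V difference within the group-significant range; both extended ±30 ms
because the cluster times are *centers* of 60 ms training windows.

## 4. Group-level cluster inference

Per time sample, participants are resampled with replacement and the
median AV−V Az difference recorded; the reported statistic is the median
of those bootstrap medians with its 2.5–97.5 percentile envelope, and a
sample is significant when the lower bound exceeds zero (one-sided,
p < 0.025). One resample per bootstrap iteration is applied to all
samples, preserving each participant's timecourse (independent per-sample
resampling is available behind a flag; whether the original procedure
resampled per sample was not decidable, and the shared-resample variant is
the conservative default because it preserves within-participant temporal
covariance).

**Minimum cluster size.** The temporal-shuffling null permutes the sample
axis independently within each participant while the per-sample AV−V
pairing travels intact, reruns the per-sample test, and records the
largest significant run. The minimum cluster size is the smallest run
length whose null exceedance probability is at most 5% — i.e. clusters
must *strictly exceed* the null 95th-percentile maximum (a null quantile
of two adjacent samples yields a minimum size of three). Taking the
quantile itself as the admissible length does not control the family-wise
rate (the null maximum *equals* its 95th percentile far more often than
5%); the measured false-cluster rate of the implemented rule is checked in
the acceptance suite (≤ 7.5% over 200 null simulations).

**Robust correlation.** The percentage-bend correlation down-weights the
`bend` fraction (default 20%) of extreme points per margin via the bounded
psi function of the percentage-bend M-estimator; the p-value uses the
t-approximation on $n-2$ df. **RT bimodality** is tested by ML mixtures of
ex-Gaussians on z-scored RTs compared by BIC ($4k-1$ parameters); the
ex-Gaussian density switches to a Mills-ratio expansion when
$\sigma/\tau - (x-\mu)/\sigma > 10$, so the $\tau \to 0$ Gaussian limit is
reached without catastrophic cancellation.

## 5. The hierarchical drift-diffusion model

Each trial's likelihood is the Wiener first-passage density at the chosen
boundary: diffusion between 0 and $\alpha$ from $\beta\alpha$ with drift
$\delta$, RT shifted by the nondecision time. The density is evaluated by
series truncation with the standard small-time/large-time switching rule
at absolute tolerance $10^{-10}$; normalization over both boundaries is
verified to $10^{-6}$ and the density is cross-validated against a
bridge-corrected Euler–Maruyama simulator (KS < 0.01 at $10^5$ draws).

Drift-regression variants ($C$ = phase coherence as a proportion):

| variant | drift | nondecision time |
|---|---|---|
| `scale_late` | $\gamma_0 + \gamma_1 y_E + \gamma_2 y_L C$ | $nDT$ |
| `scale_early` | $\gamma_0 + \gamma_1 y_E C + \gamma_2 y_L$ | $nDT$ |
| `scale_both` | $\gamma_0 + \gamma_1 y_E C + \gamma_2 y_L C$ | $nDT$ |
| `early_on_ndt` | $\gamma_0 + \gamma_2 y_L C$ | $nDT + \gamma_1 y_E$ |
| `behavior_only` | $\gamma_0 + \gamma_1 s C$, $s=\pm1$ by category | $nDT$ |

Coherence enters *uncentred*. Centring was considered and rejected:
because the model has no main-effect $y_L$ term, replacing $C$ by
$C-\bar C$ removes the pure Late-amplitude contribution to drift — it
changes the model rather than reparameterizing it — and the
$y_L C$ regressor is already nearly orthogonal to the intercept since the
amplitudes are sign-symmetric across categories.

**Hierarchy and priors.** Participant parameters (per condition) are
drawn from group Gaussians. Group-mean priors: $nDT \sim U(0.01, 1)$,
$\alpha \sim U(0.01, 3)$, $\beta \sim U(0.1, 0.9)$, regression
coefficients $\sim N(0, 3)$ (read as variance 3; the weaker of the two
readings, so it constrains recovery tests less); all group SDs
$\sim U(0.01, 2)$. Amplitudes are z-scored within participant and
condition by default so the $\gamma$s are comparable across participants
(recovery tests disable this to keep estimates on the generative scale).
Inter-trial variability parameters (sv, st, sz) are deliberately absent.
Trials with $RT \le nDT$ contribute $-\infty$ log-likelihood, which pushes
$nDT$ below the fastest RT. Regression-coefficient hyperpriors are
separate per condition; `shareHyperpriors = TRUE` pools them.

**Sampler.** Adaptive Metropolis-within-Gibbs with four move types:

1. componentwise Gaussian random-walk updates of each
   participant-condition parameter (compiled sweep);
2. a joint update of the drift coefficients whose proposal covariance is
   the inverse Gram matrix of the trial-level regressors — the Early and
   Late regressors both carry the category sign and are strongly
   correlated, so axis-aligned moves alone mix poorly there;
3. group *translation* moves (shift a whole participant column and its
   group mean together; the group-prior terms cancel), which defeat the
   slow random walk of correlated group locations;
4. group *scale-expansion* moves (rescale a column's spread around its
   mean jointly with the group SD; participant-prior terms cancel against
   the Jacobian up to $\log c$), which release the funnel between group
   SDs and participant values.

Group means are Gibbs-drawn (truncated-normal or conjugate-normal), group
SDs by exact truncated inverse-gamma inversion. Proposal scales adapt
toward ~30–35% acceptance during burn-in only, so the post-burn-in chain
is a fixed-kernel Markov chain. Chains start from a deterministic
per-participant approximate-MAP search plus chain-specific jitter.
Defaults mirror the conventional protocol (5 chains × 5500 samples, 500
burn-in, thinning 50); tests and the acceptance script use 5 × 1500/300/5,
which the Gelman–Rubin diagnostic shows is sufficient at desk scale.

**Model comparison.** DIC $= \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$ at the posterior-mean participant
parameters (the likelihood-focus convention for hierarchical models).
Condition contrasts report the posterior of the group-mean difference,
its tail probability and a t statistic on the population-level draws —
both outputs are reported because the literature's "hierarchical t test"
admits either reading.

## 6. The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions the analysis assumes:

* **Design**: 720 trials per session in blocks of 60, balanced over
  2 modalities × 2 categories × 4 coherence levels (180 per
  modality-category cell); exclusion rules RT > 1.5 s (or no response),
  RT < 300 ms, |EEG| > 150 µV.
* **Behaviour**: per-trial latent amplitudes
  $y = s\,(m + \varepsilon)$, $s = \pm 1$ by category,
  $\varepsilon \sim N(0, 0.45)$; the Late mean scales linearly with
  coherence (the late component's amplitude is proportional to the
  available visual evidence) and is amplified ×1.4 in AV — the
  multisensory benefit is confined to the post-sensory representation.
  Drift follows the `scale_late` regression with group means
  $\gamma_0 = 0$, $\gamma_1 = 0.4$, $\gamma_2 = 4.0$ (late-dominant:
  the Late×coherence term contributes ~1.2 of drift vs ~0.36 from the
  Early term, matching the reported dominance of post-sensory evidence),
  $\alpha = 1.2$, $\beta = 0.5$, $nDT$ 370 ms (V) / 410 ms (AV);
  between-participant SDs 0.10/0.15/0.40/0.12/0.04/0.04. Diffusion is
  simulated by Euler–Maruyama at $dt = 0.1$ ms with a within-step
  Brownian-bridge crossing check (first-passage bias $O(dt)$ instead of
  $O(\sqrt{dt})$), verified against the closed-form density.
* **EEG**: two rank-one components — unit-norm random topographies
  (orthogonalized), Hanning time courses centred at 270 ms (width 180 ms)
  and 500 ms (width 200 ms) — driven by the *same* latents as the
  behaviour, plus Gaussian sensor noise with exponential spatial
  correlation across the channel index (length 5 channels, SD 6 µV,
  signal gain 1 µV per unit amplitude). The waveform shape and noise
  model are generator conventions; nothing downstream assumes them.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: temporally correlated (1/f) noise, eye and
muscle artifacts, volume-conduction topography structure, non-stationary
attention or fatigue drifts, lapses, and post-error slowing. Decoding
synthetic epochs is easier than decoding real EEG at matched SNR because
the noise is white in time; decoding thresholds calibrated here do not
transfer to real recordings.

## 7. Problem sizes and numerical conventions

The test suite runs everything at reduced scale chosen so the full suite
completes comfortably on one CPU: decoding tests use 4–16 channels at
50–100 Hz with 16–96 trials; cluster-test calibration uses 40 participants
× 60 samples × 200 null simulations at 100 bootstrap/permutation
iterations; parameter recovery uses 12 participants × 304 trials (point
recovery) and 25 replicates of 6 × 160 (interval calibration); model
recovery uses 20 seeds of 12 × 304 with 2 × 350/130/2 chains; the
acceptance script uses 8 × 208 with 5 × 1500/300/5 chains. The vignette
records these as the package's choices; all are parameters, not limits.

Degenerate inputs are contracts, not crashes: single-class decoding
labels, zero-variance amplitudes in the forward model, empty significant
Late ranges (fall back to the full 400–600 ms window with a warning),
RT ≤ nDT (zero likelihood), all-identical topographies (k = 1), and
single-RT posterior predictive data (defined failure message) are all
tested.

## 8. Known limitations

* The sampler is tuned for the model sizes above; hundreds of
  participants would favour gradient-based samplers.
* DIC is reported because it is the field's convention for these models;
  it shares DIC's known optimism with weak identification — the
  model-recovery acceptance check is the guard.
* The behaviour-only variant uses stimulus coding with a category-signed
  coherence slope; accuracy-coded alternatives exist and would change the
  interpretation of $\beta$.
* `early_on_ndt` applies the trial-level nDT shift exactly in the
  likelihood but uses the mean shift in posterior-predictive simulation.
* The permutation threshold pools null Az values across windows into one
  participant-level threshold; per-window thresholds would be stricter at
  the edges of the epoch.
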