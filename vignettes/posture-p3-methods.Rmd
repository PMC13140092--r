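---
title: "Methods: simulating and analyzing P3 oddball ERPs under postural load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing P3 oddball ERPs under postural load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postureP3)
```

## The scientific question

Quiet standing is not cognitively free: maintaining posture competes with
concurrent tasks for attentional resources. A standard way to probe this is
a dual-task auditory oddball paradigm: participants stand or sit while
hearing a stream of frequent standard tones, rare target tones and novel
distractor sounds, responding by button press to standards and targets. The
parietal P3b component of the event-related potential (ERP), measured at Pz
in the 250-550 ms window, indexes the attentional evaluation of task
stimuli; a smaller P3b while standing indicates resources diverted to
postural control. `postureP3` implements the full analysis chain for this
design -- and, because mobile-EEG datasets of this kind are rarely public, a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, so that every stage is testable end to end.

The pipeline has six stages:

1. **simulate** -- oddball stimulus sequences, behavioral responses, and
   continuous 8-channel EEG written as EDF plus a BIDS-like events table;
2. **preprocess** -- 0.1-30 Hz zero-phase filtering, epoching to
   [-200, 800) ms, baseline correction, +/-100 uV artifact rejection;
3. **measure** -- per-condition ERP averages, rare - frequent difference
   waves, mean amplitude and 50 % fractional-area latency, paired
   signed-rank / t comparisons;
4. **decode** -- time-resolved standing-vs-sitting classification with
   averaged pseudo-trials and a per-timepoint linear SVM;
5. **clusterstat** -- cluster-mass permutation inference on the decoding
   accuracy time course;
6. **quality** -- analytic (aSME) and bootstrapped (bSME) standardized
   measurement error.

## The synthetic cohort

### Stimulus design

A run is 50 trials: 40 frequent (80 %), 5 rare (10 %), 5 novelty (10 %),
inter-stimulus interval 1900 +/- 200 ms (uniform jitter), with the
constraint that every rare or novelty stimulus immediately follows a
frequent one. The generator enforces the constraint by construction:
deviants are assigned to distinct "slots" after frequent trials, so no two
deviants are adjacent and a run never opens with a deviant.

### ERP model

Each component (P1, N1 at ~100 ms, P2 at ~175 ms, N2, P3) is a Gaussian
bump: per-channel amplitude times `exp(-(t - peak)^2 / (2 sd^2))` with
`sd = width / 2.355`. Gaussians are smooth, cheap, and -- crucially for
testing -- analytically known, so noise-free recordings can be checked for
exact template recovery. The P3 topography is class-specific: a parietal
P3b (maximal at Pz and CPz) for frequent and rare tones, about four times
larger for the rare targets, and a frontal P3a (maximal at Fz/FCz) for
novel sounds, matching where the univariate analysis measures each
component (P3b at Pz, P3a at Fz).

The **postural condition effect** is modeled as a gain change of the P3b
generator: additive standing-condition offsets at every channel
proportional to the canonical P3b topography, normalized so the offset at
Pz equals the `p3b_effect_uV` parameter (default -0.7 uV, the direction
and magnitude of the reported rare-tone amplitude difference). A
physiological amplitude modulation scales a component's whole scalp
projection; an isolated single-electrode change would be dipole-physically
implausible and would also understate what a multivariate decoder can see.
The true effect magnitude behind the observed ~0.7 uV group difference is
unknowable from group summaries, so it is exposed as a free parameter
rather than asserted.

Between-subject variability enters as a participant-level multiplicative
P3 gain, `N(1, 0.35)`, shared between conditions. At the default rare-P3b
amplitude of 8 uV at Pz this yields a between-subject amplitude SD of
about 2.8 uV, the scale of the reported group SDs. Because the gain is
shared across conditions it cancels exactly in within-participant
condition differences, leaving paired tests to fight only measurement
noise -- the same structure that makes within-participant designs
powerful in practice.

### Noise model and its calibration

Background activity is 1/f ("pink") noise: white Gaussian noise shaped in
the frequency domain with amplitude `1/sqrt(max(f, 1 Hz))`, no DC, scaled
to a target per-sample SD. Two anchors fix the noise scale *a priori*:

* **Amplitude**: the reported data quality of this paradigm -- aSME of
  roughly 0.7-0.8 uV for the frequent-tone P3 mean amplitude at Pz with
  ~40 clean trials -- implies a single-trial window-mean SD near 4.5-5 uV.
  With the pink spectrum above, an instantaneous SD of 6 uV per channel
  reproduces that (the package's default). The same value is used for
  both conditions so that, with a zero effect, standing and sitting are
  exchangeable by construction -- the null the decoding calibration needs.
* **Spatial correlation**: referenced scalp recordings share the
  reference electrode's signal and volume-conducted sources, so
  between-channel noise correlations are high; the generator uses 0.8,
  realized as one shared 1/f source per trial plus an independent source
  per channel (`sqrt(0.8) * shared + sqrt(0.2) * own`). The mixing leaves
  every per-channel marginal SD unchanged, so the univariate anchors are
  unaffected.

**Artifacts** are modeled as a square +/-150 uV excursion on one random
channel spanning 200-600 ms post-onset. Because 150 uV clears the
+/-100 uV gate even against worst-case background noise, the
rejection-rate calibration is exact in expectation rather than depending
on the noise amplitude. Contamination is heterogeneous across
participants: each participant has a latent noisiness quantile (shared
between conditions -- noisy participants are noisy seated too), mapped
through a Beta distribution whose mean is the condition's cohort rate,
919/6300 standing and 215/6300 sitting. A uniform rate could not satisfy
the emulated study's bookkeeping jointly: rejecting 14.59 % of standing
epochs uniformly would leave only ~25 % of participants with the 36
clean frequent epochs the decoding analysis requires, whereas that study
retained 70.63 %. With Beta concentration 1 (the default) the generator
reproduces both the cohort-mean rejection rates and an inclusion
fraction near 70 % -- most rejections come from a noisy minority, as in
real mobile-EEG cohorts.

**Behavior**: responses are produced with probability `1 - lapse_rate`
(default 0.1) and reaction times drawn from condition- and class-specific
normals (frequent: 409 +/- 158 ms standing, 448 +/- 159 sitting; rare:
595 +/- 195 vs 540 +/- 157), truncated at a 150 ms physiological floor.

**Seeds**: a master seed spawns per-(participant, condition, purpose)
child streams through `derive_seed()`, a documented congruential scheme
modulo 2^31 - 1. Every generator is a pure function of its inputs and
seed; cohorts and whole pipeline runs are bit-reproducible.

### What the generator does not emulate

No forward head-model (channels have idealized topographies, not
leadfields), no eye blinks or EMG spectra (artifacts are square pulses),
no postural sway coupling, no trial-to-trial latency jitter, and no
condition differences outside the P3b. Passing calibration tests on this
generator therefore demonstrates that the *analysis machinery* is
unbiased and calibrated under realistic SNR -- not that real standing
data would behave this way. In particular, real postural decoding signals
are broader than a P3b amplitude change (see "Known limitations").

## Preprocessing choices

* **Time grid**: epochs live on the half-open grid [-200, 800) ms sampled
  at `t = -200 + 4k` ms -- exactly 250 samples at 250 Hz with stimulus
  onset on a grid point. All windowed measures (baseline, P3 window)
  reuse the same start-inclusive, end-exclusive rule.
* **Filter**: a linear-phase Hamming-window FIR band-pass applied in one
  pass with exact group-delay compensation (zero phase). Transition
  bandwidth is `low_hz` at the low edge and 7.5 Hz at the high edge, with
  half-amplitude cutoffs half a transition band outside the pass band and
  the Hamming order rule `ceil(3.3 / (transition / rate))`; the kernel's
  mean is subtracted to zero the DC gain exactly. These mirror common
  EEG-toolbox defaults.
* **Rejection**: an epoch is flagged iff any sample on any channel
  *strictly* exceeds the threshold ("+/-100 uV" read as a tolerance
  band, so exactly 100.0 uV is retained). Rejection only flags -- the
  epoch count always equals the event count -- and edge-truncated epochs
  carry the distinct reason `"edge"` for auditable reports. Rejection is
  assessed on the filtered signal. Commercial artifact-reconstruction
  steps (ASR-style cleaning) are intentionally out of scope; the
  amplitude gate alone defines "clean" here.

## ERP measures

Mean amplitude is the arithmetic mean over in-window samples. The
fractional-area latency rectifies the waveform at zero (positive area
only -- the P3 is positive-going and this is the common ERP-toolbox
convention; the fraction and window are arguments), accumulates trapezoid
area on the sampling grid, and solves for the crossing *exactly* on the
piecewise-quadratic cumulative area implied by linear interpolation of
the rectified samples. When the window holds no positive area the latency
is undefined and returned as `NA`, never a sentinel value. Tests verify
the crossing against an independent brute-force integrator on a 0.001 ms
grid.

Paired condition comparisons use the Wilcoxon signed rank for amplitudes
(exact two-sided p by dynamic programming over sign assignments for up to
25 nonzero differences -- correct under ties, where the textbook exact
distribution does not apply -- and a tie-corrected normal approximation
with continuity correction beyond) and the dependent t-test for
latencies. Missing pairs are dropped listwise and counted.

## Decoding

Per participant, per timepoint, standing vs sitting is classified from
the 8 channel voltages with a soft-margin linear SVM (cost 1, no feature
scaling -- all features are microvolts on one scale). Trials are
equalized: exactly 36 clean frequent epochs (or 45 merged) per condition
are drawn without replacement and partitioned into 3 disjoint groups of
12 (15), each averaged into one pseudo-trial; every fold serves as test
once, and the whole assignment is re-randomized over iterations (100 in
the full design). Accuracy is the proportion of correctly classified test
cases, and every prediction is stored so permutation inference never
retrains. Participants below the trial threshold in either condition are
excluded with a log entry, matching the inclusion bookkeeping of the
emulated study (36 and 45 are the published thresholds; the equalized
count is fixed at the threshold for everyone, which is what makes "12
per average" a constant).

Implementation notes: the SVM is a small deterministic SMO solver in
compiled code -- training sets here have 4 cases, but calibration suites
need on the order of 10^5-10^6 fits, which rules out per-fit calls into a
general-purpose library; tests cross-check its predictions against both a
nearest-class-mean oracle and an independent SVM implementation
(`e1071`), with exact agreement in practice. Test cases falling exactly
on the decision boundary are assigned the first-listed class (standing)
-- a deterministic, documented bias that label permutation would expose
if it mattered. The kernel, cost and scaling are defaults, chosen
because the emulated analysis names only its toolbox's default trainer.

## Cluster-mass permutation inference

Per-participant accuracy time courses are smoothed with a centered
5-point running average (window clipped at the series edges, so constant
series are unchanged), then each post-stimulus timepoint is tested
across participants against chance (0.5) with a one-tailed one-sample
t-test at alpha = 0.05 -- one-tailed because below-chance decoding is not
meaningful for this design. Runs of consecutive significant timepoints
form clusters scored by summed t ("t-mass"); single-point clusters are
allowed, since the permutation correction, not a length rule, controls
error. Smoothing is applied to *per-participant* series before the
group test, identically for observed and permuted data, so the two
pipelines differ only in labels.

The null distribution permutes the stored test-set labels within each
(participant, iteration, fold) block -- the exchangeability unit of the
stored predictions, which also preserves each fold's class balance --
recomputes accuracy from the stored predictions (no retraining), and
repeats the smoothing/testing/clustering verbatim, recording the largest
cluster mass per permutation (zero if none). With 1000 permutations the
p-resolution is 0.001; an observed mass exceeding every null mass is
reported as "<0.001". A cluster is significant when its mass lies above
the 95th percentile of the null (equivalently, unfloored p < alpha).
Because each fold's two test cases carry one label of each class, a
block permutation either keeps or swaps the pair, and a swap flips the
correctness of both predictions -- which reduces the whole null to
per-participant matrix products and makes 1000 permutations essentially
free.

## Data quality

The aSME is the sample SD (n-1) of single-trial window-mean amplitudes
divided by sqrt(N) -- the standard error of the participant's amplitude
score. The fractional-area latency is a nonlinear functional of the
*averaged* waveform, so its precision is estimated by bootstrap (bSME):
resample the cell's epochs with replacement, average, recompute the
latency, and take the SD over replicates (10,000 in the full design;
pipeline and test runs use fewer, see below). Replicates with undefined
latency are dropped and counted, never imputed, to keep sentinel values
out of the SD. Following the emulated analysis, the bSME cell pools
frequent, rare and novelty epochs of one condition; per-class values are
available through the `class` argument.

## Problem sizes used by the test suite

The packaged checks scale the full design down to keep the suite fast
while preserving every structural property: chance calibration uses 20
participants x 20 iterations; familywise-error calibration uses 200 null
cohorts of 20 participants with 5 iterations and 200 permutations;
effect-recovery uses 50 cohorts of 30 participants with 30 iterations
and 200 permutations; the demonstration pipeline runs 12 participants,
20 iterations, 200 permutations and 500 bootstrap replicates. Iteration,
permutation and bootstrap counts only sharpen estimates -- they do not
change what is being estimated -- so these reductions trade precision,
not validity. The full-scale constants (100 iterations, 1000
permutations, 10,000 bootstrap replicates) remain the defaults of
`decoding_spec()`, `cluster_test()` and `bsme()`.

## Known limitations

* With noise calibrated to the reported data quality and the condition
  effect confined to the P3b component, per-timepoint decoding
  accuracies sit near 0.52-0.53 for a 1 uV effect -- consistent with the
  0.54-0.59 accuracies reported for the real data, which reached
  significance with ~89 participants. At 30 participants the cluster
  test then detects the effect in roughly 60 % of replicates, not 80 %:
  real postural decoding draws on condition differences far broader than
  a P3b amplitude change (the emulated study decoded *frequent* trials
  above chance from ~100 ms onward even though their univariate P3
  difference was ~0.03 uV). The generator deliberately does not inflate
  its effect structure beyond the P3b parameter to make this scenario
  easier.
* The signed-rank power of the univariate P3b comparison at 30
  participants and a -1 uV effect is about 85-90 % under the same
  conditions.
* EDF output quantizes to 16 bits over +/-400 uV (~0.012 uV steps);
  round-trip tests use that tolerance.
* The cluster test assumes participants are exchangeable under the null
  and controls familywise error over time only (no channel-adjacency
  clustering -- decoding already pools channels).

## Reproducing the packaged numbers

`scripts/acceptance.R` regenerates the pipeline's headline calibration
quantity from scratch (chance-level grand-average decoding accuracy on an
exchangeable 20-participant cohort) and writes it as JSON; see the README
for invocation. All cohort, decoding and inference parameters above are
the package defaults, so `run_pipeline(run_config(seed = 1), out)`
reproduces a complete worked example deterministically.
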