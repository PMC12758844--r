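---
title: "Dissociating feedforward and feedback information: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating feedforward and feedback information: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When an observer identifies an object seen in the visual periphery, information
about that object is fed back from high-level object-processing regions to
early visual cortex — including foveal V1, which receives no direct stimulus
input in this task. Two properties of feedback make it separable from
feedforward processing:

* **Space (laminar profile).** Feedforward input targets the middle cortical
  layer; feedback arrives in the deep and superficial layers. With
  submillimeter fMRI, a voxel's volume fractions across depths let effects be
  assigned to layers.
* **Time and retinotopy.** Feedforward responses are locked to the stimulated
  retinotopic location; feedback converges onto the same (foveal) cortex
  regardless of where the objects appeared. A classifier trained on trials
  from one pair of stimulus locations and tested on the other pair can
  therefore only succeed on location-invariant — feedback — information, and
  it succeeds later in time.

`laminarflow` implements this analysis chain: vasculature cleanup and
leave-one-run-out laminar decoding of block-wise fMRI responses; time-resolved
pseudo-trial decoding of source-space MEG epochs with same-location and
cross-location schemes; per-trial representational strength (signed distance
to the decoding hyperplane); conditional Granger causality between regions
with a pre-stimulus baseline; trial-wise correlation of strength with reaction
time; and the group-level significance machinery (one-sample tests, BH-FDR
with an explicit family size, cluster-based sign-flip permutation). A
synthetic-data module generates both input kinds with fully known ground
truth, so every stage is validated end to end without any data download.

# The synthetic-data generators

The generators define the study conditions the validation suite runs under.
They are first-class, tested code, not fixtures.

## Laminar fMRI tables

Each subject contributes one table per ROI (foveal V1, peripheral V1, LOC,
pIPS; 600 voxels each by default). The block design has 12 runs with one block
per condition per task per run (8 blocks/run): conditions are category
(cubie/smoothie) x orientation (vertical/horizontal), tasks are peripheral and
foveal. Per voxel:

* **Layer fractions** are drawn from a Dirichlet concentrated on one randomly
  chosen compartment out of {WM, CSF, deep, middle, superficial}
  (concentration 8 on the dominant compartment, 0.5 elsewhere; dominant
  fraction 0.8 in expectation). This mimics voxels sampled across a laminar
  ribbon without simulating equi-volume geometry.
* **Condition effects** are added along a fixed unit pattern vector per
  (ROI, feature), weighted by the voxel's volume fraction of the layers that
  carry the feature according to the information profile. Class signs are
  +pattern for one class and -pattern for the other, which makes linear
  separability explicit. The default profile plants the laminar map under
  study: foveal-V1 category in deep + superficial (feedback), foveal-V1
  orientation in deep only; peripheral-V1 orientation in middle + superficial
  (feedforward), no peripheral-V1 category; LOC and pIPS category in middle +
  superficial. Amplitudes default to 3x the beta noise SD.
* **Veins.** A planted fraction (default 10%) of voxels get a positive beta
  shift (+1 response unit), doubled beta noise, and a -150 intensity shift of
  mean EPI; mean EPI also carries a linear spatial trend (slope 5 per mm) plus
  intensity noise (SD 20). The planted mask is the recovery target for the
  exclusion step.

## MEG-like epoch sets

Each subject contributes a trial x source x time array at 100 Hz over
[-0.3, 0.8] s, with 104 trials per condition at each of two location sets
(A/B) and three regions (early visual, occipitotemporal, posterior parietal;
60 sources each by default). Each signal component is

> class sign x amplitude x spatial pattern x temporal envelope x per-trial gain,

with a raised-cosine envelope (50 ms rise, 300 ms sustain, 100 ms fall) from
the component's onset. Patterns within a region are orthonormal. Feedforward
patterns in the early visual and parietal regions differ (are orthogonal)
between location sets; occipitotemporal patterns are location-invariant. The
early-visual *feedback* component (onset 0.22 s for category, 0.25 s for
orientation) uses a location-invariant pattern orthogonal to the same-region
feedforward patterns, and its per-trial gain is the occipitotemporal gain
series delayed by 30 ms. That lagged gain coupling is exactly what the
conditional Granger analysis must recover, and the feedback onsets are what
the latency and onset analyses must recover.

**Gain model.** Gains are positive log-normal deviates, `exp(gain_sd * z)`
with `gain_sd = 0.7` by default and `z` white in time. We deliberately default
to white (temporally uncorrelated) gains: if the gain series is smooth in
time, the noisy occipitotemporal strength series predicts the early-visual
series in *both* time directions — additional noisy replicas of an
autocorrelated process reduce prediction error regardless of causal order —
and no analysis can then pass a time-reversal direction control. With white
gains the planted coupling is strictly causal at the stated lag (which is
constrained to a whole number of samples), so direction controls are
meaningful. A smoothing width remains available in the configuration for
users who want autocorrelated gains.

**Behavior.** Reaction time is `0.9 - 0.3 x (mean planted category-feedback
strength in [0.22, 0.42] s) + noise (SD 0.1 s)`, floored at 0.2 s; correctness
is Bernoulli with probability increasing in the same strength (about 65%
correct on average, in the range of the behavioral accuracy such peripheral
discrimination tasks yield). Only the category feature drives behavior, so
the orientation-strength correlation is null by construction — mirroring the
dissociation under study.

**What the generators do not emulate:** sensor forward models and
cross-region source leakage, hemodynamic convolution and autocorrelated fMRI
noise, eye movements, learning or adaptation across trials, and
participant-level heterogeneity beyond independent noise. Passing tests
therefore validate the *analysis machinery* — recovery of planted structure
at realistic SNR — not the empirical claims of any particular dataset.

# Analysis methods and the choices behind them

## Vasculature cleanup (fMRI)

Large ascending veins inflate beta amplitudes and darken T2*-weighted EPI.
Two criteria flag voxels, each from a two-component Gaussian mixture fitted
by EM (median-split initialization, log-likelihood tolerance 1e-6, at most
500 iterations, components sorted by mean): membership (by maximum posterior
responsibility) in the higher-mean component of per-voxel mean betas, or in
the lower-mean component of spatially detrended mean EPI (OLS on 1, x, y, z).
A criterion only applies when its mixture separation — absolute mean gap over
the weight-pooled SD — is at least 2: a two-component fit on unimodal data
splits arbitrarily, and the gate keeps such fits from excluding anything.
Mean betas are condition-agnostic, so the exclusion leaks no labels even
though it is computed once per table.

## Laminar decoding (fMRI)

Voxels are assigned to deep/middle/superficial by dominant volume fraction
(WM- or CSF-dominant voxels are excluded; exact ties resolve deep > middle >
superficial). Decoding is leave-one-run-out: within training runs,
same-condition blocks are averaged per run; the top 500 voxels (whole ROI) or
top 300 (within a layer; all voxels if fewer) are selected by absolute
two-sample t on training samples only; columns are mean-centered with
training means; a linear SVM (libsvm, C = 1, no further scaling) classifies
the held-out run's per-condition averages. Both non-target conditions
contribute samples (decoding category uses both orientations, and vice
versa). Decision ties count as errors. We rank by |t| rather than signed t —
both directions of a difference are informative for a linear classifier.

## Time-resolved decoding (MEG)

Trials of each condition cell are randomly partitioned into 8 splits and
averaged into pseudo-trials; partitions are re-drawn on each of the repeats
(default 20), and the repeat average is reported. At each time point the 100
most informative sources are selected by one-way ANOVA F across the four
condition cells, on training samples only, recomputed per time point to avoid
test leakage. Same-location decoding pools both location sets into the split
structure and leaves one split out; cross-location decoding trains on all
pseudo-trials of one location set and tests on the other, averaging both
directions (the design is symmetric). Accuracy curves are smoothed with a
Gaussian kernel whose half-width-at-half-maximum is 100 ms (the conventional
reading of "half-width"; recorded in the output), normalized as
`(accuracy - chance) / (peak - chance)` with the peak restricted to t > 0
(pre-stimulus accuracy is noise), and the latency is the first
linearly-interpolated crossing of 75% of the above-chance peak at or after
stimulus onset. Latency is computed on the group-mean curve by default — the
group curve is far less noisy than per-subject curves at desk-scale sizes —
but per-subject estimation is available by applying the same functions per
subject.

## Representational strength and conditional Granger causality

The strength of a representation in a trial is the signed geometric margin:
the decision value of the trained hyperplane divided by the weight norm,
positive toward the trial's true class. Strengths are computed on raw trials
(pseudo-trials would destroy the trial resolution the behavioral analysis
needs), with the cross-location scheme by default: each trial is scored by
the hyperplane trained on the opposite location set, which isolates the
location-invariant (feedback) component in retinotopic cortex. Per time
point, strengths are z-scored across trials.

Granger influence from a source region to a target region at evaluation time
t pools regression samples over trials and the window's time points within
(t - 150 ms, t]. The full model regresses the target on 5 lags (10-50 ms at
100 Hz) of itself, of the source, and of every other region (so each pair is
conditioned on the third); the reduced model omits the source lags. Both are
ordinary least squares on identical samples, so the influence
`ln(U_reduced / U_full)` (U = residual mean square) is non-negative by
construction. Pooling across the window treats samples as exchangeable within
it — a sliding-window, locally stationary reading. The pre-stimulus baseline
applies the same model to evaluation times in (-50, 0] ms (the earliest times
whose windows and lags fit inside [-0.3, 0]) and summarizes them as one
scalar per subject; subject-level effect series (influence minus baseline)
enter a one-tailed cluster permutation over post-stimulus times, and the
onset is the start of the earliest significant cluster. Influence curves may
be smoothed (half-width 50 ms) for display only, never before inference.

## Behavioral correlation

Per condition (category x orientation, location sets pooled): only correct
trials enter; trials with reaction time beyond 2 SD of the condition mean are
excluded; at each time point, trials that are misclassified (negative
distance) with magnitude beyond 2 SD of that time point's distances are also
excluded — we read the "incorrectly classified with high distance" rule as
applying to misclassified trials only, since a large *positive* distance is a
good representation, not an outlier. The reported value is minus the Pearson
correlation between distance and reaction time, so positive values mean
better representation, faster response; values are averaged over the four
conditions and smoothed (half-width 100 ms). Reaction-time exclusion SDs are
computed within condition and subject because conditions differ in
difficulty.

## Significance machinery

One-sample t-tests (one-tailed against chance for decoding; two-tailed where
a signed difference is the question) feed Benjamini-Hochberg FDR with an
explicit family size `m`, so a subset of tests can be corrected against the
full stated family (the laminar analysis uses m = 24: 4 ROIs x 3 layers x 2
features within a task). For time courses, clusters are maximal runs of time
points whose group t passes the cluster-forming threshold; the cluster mass
sums the t-values over the run (scale-free across regions, the field-standard
choice where "summed effects" is ambiguous); the null distribution is the
maximum cluster mass under independent whole-course sign flips per subject
(default 50,000; studies here use 2,000), and cluster p-values carry the +1
correction so they are never exactly zero.

# Numerical choices and degenerate inputs

* EM: SD floor of 1e-6 x sample SD per component; zero-variance samples and
  n < 20 are errors; non-converged fits are reported with their flag.
* Rank-deficient EPI detrending falls back to mean-centering with a warning;
  singular Granger designs fall back to ridge with penalty 1e-8 and a
  warning.
* Features with zero within-group variance get infinite F (ranked first,
  warned) if their means differ, F = 0 (ranked last) otherwise.
* Decision ties at the hyperplane count as errors (conservative and
  deterministic).
* Time is stored in seconds with samples at exact multiples of 1/sfreq;
  smoothing uses reflected-boundary padding and leaves missing values
  missing via normalized convolution.
* All randomness is seeded; identical configuration + seed reproduces arrays
  bit-for-bit and result files byte-for-byte.

# Validation studies and their problem sizes

The package ships study functions that regenerate data and measure recovery;
`scripts/acceptance.R` runs them all. Sizes were fixed once for desk-scale
runtime on one CPU:

| Study | Size |
|---|---|
| Chance calibration | 50 label permutations per arm (1 subject each) |
| Laminar map + 24-test FDR | 18 subjects, 4 ROIs x 600 voxels |
| Vasculature recovery | 1 subject, 4 ROIs; plus a zero-vein control |
| Latency dissociation | 6 subjects, full-size epochs, 2 repeats |
| Granger direction/onset | 10 replicates x 8 subjects, 32 trials/condition, 30 sources/region, 2,000 flips |
| Analytic Granger oracle | 500 trials, closed form ln(1 + b^2 var(x)/var(e)) |
| Cluster type-I | 20 null replicates, 15 subjects x 100 time points, 2,000 flips |
| Behavior link | 8 subjects, planted slope 0.3 s/unit and null slope |

# Known limitations

* The linear-SVM margins come from libsvm with its default optimizer
  tolerance (1e-3); distances are exact given the fitted hyperplane but the
  hyperplane itself is a numerical optimum.
* The Granger model assumes local stationarity within the 150 ms window;
  onsets are therefore detected with a lag of roughly the time the coupled
  samples need to dominate the window, which bounds onset precision to a few
  tens of milliseconds.
* The pre-stimulus Granger baseline at a 1.1 s epoch yields only five
  evaluation points; the per-subject scalar mean is the stable statistic, a
  per-time-point baseline is not.
* With few subjects, the cluster-forming t threshold is high (t_7 at p = .01
  is 3.0); real studies with 15+ participants have correspondingly more
  sensitive cluster inference.
* The RDS-based container is R-specific; it preserves the logical layout
  (/fmri/subject/..., /meg/subject/..., ground truth alongside) and
  round-trips bit-exactly, but is not a cross-language interchange format.
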