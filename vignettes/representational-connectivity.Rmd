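---
title: "Representational similarity and time-lagged connectivity: models, choices, and limits"
author: "repconn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational similarity and time-lagged connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repconn)
```

## The scientific problem

Multichannel neural recordings (MEG sensor arrays, source-localised
vertices, fMRI voxels) carry distributed activity patterns whose
*similarity structure* across stimuli can be compared with explicit
models of stimulus properties.  A representational dissimilarity matrix
(RDM) summarises, for every pair of items, how different the evoked
patterns are; a model RDM does the same for a feature space — for
example the nodal activations of an artificial neural network layer
(Pearson correlation distance) or binary semantic feature norms (cosine
distance).  Representational similarity analysis (RSA) asks whether the
neural RDM carries the model's geometry; time-resolved RSA asks *when*.

Representational connectivity analysis (RCA) goes one step further and
asks *where the geometry came from*: does the earlier representational
state of a source region help explain the current model-related
geometry of a target region?  This is a Granger-style question posed
entirely at the level of representational dissimilarity vectors (RDVs),
not raw signals.

## The statistics implemented

**Partial Spearman correlation** (`partial_spearman`).  All vectors are
rank-transformed with average ranks for ties; target and model ranks are
residualised on the covariate ranks (least squares, with intercept);
the statistic is the Pearson correlation of the residuals.  With no
covariates this is textbook Spearman.  Covariate sets that become
rank-deficient are handled by the pivoted QR — dependent covariates
simply contribute nothing.  Zero-variance residuals return 0: this is a
deliberate convention for the degenerate case where a covariate
coincides with the target or the model (the unique effect really is
nothing), and it is flagged with a warning.

**RSA time-courses** (`sliding_window_rdms`, `rsa_timecourse`).  The
pattern for an item at timepoint *t* is the channels-by-window block
centred on *t* (default 40 ms, realised as the nearest odd number of
samples), flattened channels-major; the neural RDM entry is one minus
the Pearson correlation of two item patterns.  Flattening order does not
affect the statistic (Pearson distance is permutation-invariant), only
serialisation.  Timepoints whose window would cross the epoch edge are
marked invalid rather than zero-padded, so no spurious early or late
effects can arise; invalid timepoints propagate as `NA` and clusters
can never bridge them.  One trial per item is assumed (each stimulus
shown once); if several trials per item are supplied they must be
averaged within item upstream.

**Cluster-mass permutation inference** (`cluster_test_temporal`,
`cluster_test_spatiotemporal`).  A one-sample t-test against zero is
formed at every timepoint (and point, for searchlights); contiguous
supra-threshold runs (cluster-forming alpha 0.01, positive tail by
default, two-sided available) are summarised by the sum of their
t-values (cluster mass).  The null distribution is the maximum cluster
mass after flipping the sign of each subject's whole time-course at
random; the observed statistic is included in the reference set, so a
p-value can never be zero and is bounded below by 1/(permutations + 1).
When `2^subjects` does not exceed the requested permutation count the
full sign enumeration is used and p-values are exact.  The positive
tail is the default because the substantive hypotheses here are about
the *presence* of model information (negative "information" has no
interpretation in this framework); the two-sided variant exists for
contrasts.  Spatiotemporal clusters connect supra-threshold elements at
the same point across consecutive timepoints and across adjacent points
at the same timepoint; with a single point the test reduces exactly to
the temporal one.

**Peak-latency jackknife** (`jackknife_peak_ci`).  Every
leave-4-out subset of the subject pool yields a group-average
time-course and a peak time (first occurrence on ties, searched in
post-stimulus time by default); the 95% CI of a latency difference is
the 2.5th/97.5th percentile of the resample distribution of
differences.  `count_resamples` exposes the exact enumeration count
(31,465 for a pool of 31 with 4 left out; 58,905 for a pool of 36).
The enumeration is capped (default 100,000) with seeded subsampling
beyond the cap, and the result is flagged when subsampled.

**RCA flow** (`rca_flow`).  At each timepoint *t* two partial Spearman
correlations between the target region's RDV and the model RDV are
computed: the first controls for the other model RDVs (and, in the
multivariate variant, the lagged RDVs of control regions); the second
additionally controls for the source region's RDVs at every lag in a
window of strictly negative offsets (default −30 to −2 ms at the
sampling step, each lag one covariate).  The flow is the difference.
Single-timepoint RDMs are used so that lagged source RDVs never share
samples with the current target RDV.  The target's own history is not
partialled out, and lags are rounded to the sampling grid with a
warning when they do not divide evenly.  Undefined early timepoints
(lag window before the epoch start) are `NA` and excluded from cluster
forming.

**Group and connection contrasts** (`rca_group_contrast`,
`rca_connection_contrast`, `median_split`).  Independent groups (e.g. a
median split of subjects by mean response time) are compared with
pooled-variance two-sample t-tests per timepoint and a label-exchange
permutation scheme; the cluster-forming level defaults to 0.05 here
because between-subject contrasts carry much less power than
within-subject tests.  Paired comparisons of two connections feed the
per-subject difference time-courses to the sign-flip machinery.

## What the synthetic generator emulates

`simulate_epochs` produces, per subject and region, an items x channels
x time array: i.i.d. Gaussian sensor noise plus injected item-specific
signals.

* **Geometry.**  Each model's RDM is embedded as unit-norm item
  coordinates (eigendecomposition of the similarity matrix `1 − D`,
  non-negative components); per subject these are mixed into channel
  space through a random orthonormal, mean-free basis.  Mean-free
  mixing makes the sample Pearson correlation of two pattern rows equal
  their latent inner product, so the embedded patterns reproduce the
  source RDM exactly whenever `1 − D` is positive semi-definite (true
  for every correlation-distance RDM).  Item geometry is shared across
  subjects; channel topography is not — matching the group-RSA
  assumption of shared geometry without shared sensors.
* **Envelope.**  Injections follow a Hanning window over
  `[onset, onset + duration]`: a smooth evoked-like morphology with no
  edge artefacts.  The stimulus-locked envelope shape of real effects
  is unknown; this is a convention, not a claim about data.
* **SNR convention.**  `snr` is the ratio of the injected signal's
  per-channel RMS at the envelope peak to the noise standard deviation
  — a concrete, testable definition.
* **Representational innovations.**  A fraction
  (`pattern_jitter_frac`, default 0.8) of the injected signal energy is
  item-specific pattern jitter redrawn at every sample; the remainder
  is the static model geometry.  This innovation process is essential:
  time-lagged flow can only be direction-specific if the transmitted
  content is partly unpredictable from moment to moment, exactly as
  Granger causality is undefined for deterministic signals.  A purely
  static injected geometry is equally well explained from either
  region's past, and simulations confirm that both flow directions then
  light up.  The default of 0.8 reflects that most moment-to-moment
  pattern variance in real recordings is not model-locked, while
  keeping single-run RSA effects comfortably detectable.
* **Coupling.**  A coupling adds a gain-scaled, lag-shifted copy of the
  source region's *clean* signal (static geometry plus jitter, not the
  sensor noise) to the target's channels through a random orthonormal
  projection.  Signals propagate sample by sample in time order, so
  chains (P to M to A) and bidirectional loops resolve naturally with
  summed lags.  Sensor noise does not propagate: RCA's premise is that
  representational content, not measurement noise, flows between
  regions.
* **Behaviour.**  Couplings marked `feedback` receive per-subject gain
  jitter (clipped to `[0, 1]`); each subject's mean response time is a
  linear function of their mean feedback gain plus Gaussian noise.
  Linear-Gaussian generation is the simplest mechanism producing the
  qualitative pattern of interest (slower responders show stronger
  feedback flow).
* **Determinism.**  All randomness derives from one master seed through
  a fixed multiplicative-congruential child-seed scheme
  (`child_seed`), so identical scenarios regenerate bit-identically
  and stages never share RNG streams.

What the generator deliberately does **not** emulate: biophysical
forward models, realistic sensor geometry, 1/f or correlated noise,
artefacts, trial-order effects, or oscillatory dynamics.  Passing tests
on this generator therefore demonstrate that the estimators recover the
structure they are defined on — not that real data satisfy the
generator's assumptions.

## Validation studies and their sizes

The test suite validates each estimator against ground truth at desk
scale: 24 items, 12 channels per region, 200 Hz sampling, epochs of
−100 to 400 ms, 20–30 subjects, 50 independent runs per property, and
1000 permutations per test (10,000 where a single test is cheap).
These sizes keep the whole suite inside a routine test run; the
corresponding real studies are an order of magnitude larger (hundreds
of items, hundreds of sensors, 500 Hz).  The properties checked:
type-I control of the cluster test under the null; recovery of injected
latencies and of the direction of lagged coupling; shrinkage of
indirect-chain flow when the relay region is partialled out; and
detection of behaviourally coupled feedback differences after a median
split.

Two honest limitations surfaced by these studies are worth stating.
First, the difference-of-partial-correlations flow retains a small
second-order leak in the uncoupled direction whenever both regions
carry the same static model geometry: lagged RDVs of the *target* of a
coupling are weak but genuine predictors of the model RDV, so
partialling them removes a share (quadratic in their RDV-model
correlation) of the source's model correlation.  At the simulated SNR
this leak is roughly one twentieth of the forward flow but is
occasionally cluster-significant with 20 subjects; feedback clusters
observed during strong feedforward epochs should be interpreted with
this in mind.  Second, the percentile jackknife CI on peak-latency
differences is not a calibrated confidence interval: leave-4-out
resamples share most of their subjects, so the percentile spread
under-represents replication variability and empirical coverage sits
slightly below nominal (85–90% in our studies), compounded by peak
quantisation on the sampling grid when group curves are very clean.

## Numerical and design choices

* Pearson-distance entries are clipped to `[0, 2]` and cosine-distance
  entries to `[0, 1]` against floating-point drift; RDMs are
  symmetrised and their diagonals zeroed on construction.
* RDV ordering is the row-major upper triangle, diagonal excluded;
  `devectorize` inverts it exactly.
* The posterior/anterior sensor split is a median split on the sensor
  y-coordinate: posterior takes the smaller y values, the extra channel
  on odd counts, and ties are resolved by stable channel-index order.
* Searchlight neighbourhoods use inclusive Euclidean radius with the
  centre always included; coordinates are in millimetres.
* Item masks (e.g. incorrectly named trials) must leave at least three
  items; subsetting commutes with vectorisation and is applied
  identically to model and neural objects.
* Exact sign enumeration replaces random permutation automatically when
  it is cheaper than the requested permutation count; the observed
  statistic is always part of the reference set.
* The epochs container is a plain-text directory (full-precision TSV
  matrices plus a JSON schema sidecar) that round-trips bit-identically
  and fails loudly, naming any missing field.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- read_config(system.file("extdata", "demo_config.yaml",
                               package = "repconn"))
man <- run_pipeline(cfg, out_dir = "demo_out", seed = 1)
# per-stage runtimes, output inventory:
str(man$stages)
man$outputs
```

The demo simulates two correlated models injected into a posterior
region with feedforward coupling to an anterior region, computes
partial-Spearman RSA time-courses for both models in both regions with
cluster-mass inference, runs RCA in both directions, and writes TSV
reports plus a JSON manifest sufficient to reproduce the run.
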