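---
title: "Decoding pre-movement intention from EEG: methods and design notes"
author: "movintent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding pre-movement intention from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Self-initiated limb movement is preceded by two well-established EEG
correlates. Over sensorimotor cortex, the power of the alpha (7-12 Hz)
and beta (12-30 Hz) rhythms decreases before and during movement —
event-related desynchronization (ERD). Simultaneously a slow (0.1-1 Hz)
negative potential, the movement-related cortical potential (MRCP),
builds up over central electrodes and peaks near movement onset. Both
phenomena begin before any peripheral signal, so a classifier fed with
their features can announce *intention* before the movement itself —
the premise of brain-machine interfaces that trigger rehabilitation
robotics from the patient's own motor drive.

`movintent` implements a complete offline pipeline for this problem:
synthetic data generation with planted ground truth, movement-onset
detection, epoching and artifact rejection, reference-free spatial
filtering including SNR-optimal filters, ERD/MRCP quantification,
combined feature extraction over sliding windows, sparse discriminant
classification, and event-based evaluation of the continuous decoder.

# The pipeline, stage by stage

## Onset detection and epoching

Movement onsets are found on auxiliary kinematic/EMG channels: each
channel is demeaned and rectified, channels are averaged, and onsets are
the upward crossings of 5% of the maximum amplitude (`detectOnsets()`,
with a 2 s refractory merge — trials are 13 s apart, so true onsets can
never be merged). Epochs span [-3, 3) s around each onset
(`epochTrials()`); onsets with less than 3 s of rest since the previous
onset, or without full window support, are dropped with a logged reason.

Artifact rejection (`rejectArtifacts()`) computes six measures per
trial — band power in delta, theta, alpha and beta, the variance, and
the maximum absolute amplitude — each per channel and then averaged over
channels, and rejects a trial when any measure exceeds 2.5 times the
mean of that measure across trials. Whether the historical rule operated
per channel or on channel-aggregated measures is not documented
anywhere we could find; the channel-mean variant keeps the rule
one-pass and montage-agnostic, and is exposed as a single multiplier
parameter. Rejected trials are masked, never deleted.

## Spatial filtering

Three reference-free filters are provided. The common average reference
(`carFilter()`) subtracts the instantaneous channel mean. The small
Laplacian (`laplacianFilter()`) subtracts the mean of the up-to-four
orthogonally adjacent 10/10 electrodes; edge channels use whatever
neighbours exist (edge handling is unspecified in the classical
literature; using the available subset degrades gracefully toward a
bipolar derivation at the montage border).

The SNR-optimal spatial filter (`fitOSF()`) is the interesting one. For
a weight vector $w$ over $c$ channels, epochs are band-filtered
(0.1-1 Hz for MRCP, 7-30 Hz for ERD), and split into a signal window
$[-1, 1]$ s and a noise window $[-3, -1]$ s. With per-epoch powers
$P_{S_i} = w^\top A_i w$ and $P_{N_i} = w^\top B_i w$ ($A_i, B_i$ the
epoch covariance matrices), the objective is

$$\mathrm{SNR}(w) = \frac{1}{L}\sum_{i=1}^{L}
  10\log_{10}\frac{P_{S_i}}{P_{N_i}},$$

maximized for MRCP (the slow potential is large peri-onset) and
*minimized* for ERD (oscillatory power drops before movement), subject
to $\sum_j w_j = 0$. The constraint is eliminated exactly by writing
$w = Bz$ with $B$ an orthonormal basis of the sum-zero subspace and
optimizing $z$ by BFGS with the analytic gradient

$$\nabla_w = \frac{20}{L\ln 10}\sum_i\left(\frac{A_i w}{w^\top A_i w}
  - \frac{B_i w}{w^\top B_i w}\right),$$

started from the CAR-for-channel vector ($1 - 1/c$ at Cz for MRCP, C3
for ERD, $-1/c$ elsewhere). Because the objective is scale-invariant,
converged weights are normalized to unit norm for reproducible weight
maps; this does not change the SNR. Budget: 500 iterations, relative
tolerance 1e-6. If the optimizer fails to improve on the start point,
the initial filter is returned flagged `converged = FALSE`. In
cross-validation the filters are always fitted on training trials only
and applied frozen to the held-out trial.

## ERD and MRCP quantification

`erdMap()` computes Morlet-wavelet power (7 cycles at every frequency —
the width is a free parameter in the source literature; 7 is the common
compromise between time and frequency resolution, and it is exposed as
an argument) over 1-50 Hz, averages over trials, and expresses it as
percent change against the per-frequency trial-averaged baseline power
in [-3, -1] s — the classical ERD definition, in which the reference is
computed from the trial-averaged power rather than per trial. Maps are
stored on a time grid decimated by block-averaging (default 32 Hz),
which is what makes the bootstrap affordable. `bootstrapMask()`
resamples trials with replacement (B = 1000 by default), recomputes the
percent-change map per resample, and flags cells whose percentile
interval excludes zero — percentile intervals, per cell, no
multiple-comparison correction (significance maps are descriptive
here). `premovementERD()` averages the map over a band and the last
second before onset.

`mrcpWaveform()` CAR-filters the trials, subsamples to 64 Hz
(anti-aliased), bandpass-filters to 0.1-1 Hz with a zero-phase
2nd-order Butterworth, averages over trials, and reports the negative
peak in [-1, 1] s. `normalizeMrcp()` rescales a set of movements per
channel so the movement with the largest peak magnitude sits at exactly
-1.

## Features

Every feature vector describes one 1-second window $[t-1, t)$ —
half-open, so the sample at exactly $t$ is excluded; a 64 Hz window
holds exactly 64 samples, and no sample at times $\ge t$ is used. ERD
features are Burg AR(16) power spectra evaluated at integer frequencies
7-30 Hz (24 bins) on the Laplacian-filtered sensorimotor channels (19
after the canonical FC3/FC1 exclusion: 456 features) plus the
ERD-optimal virtual channel (24 more). The 24-bin reading at 1 Hz
resolution is the only one consistent with 456 = 19 x 24. MRCP
features are the 64 time samples of the CAR-filtered, 64 Hz, 0.1-1 Hz
window on 8 central channels (512 features) plus the MRCP-optimal
virtual channel (64 more) — 1056 in total, shrinking predictably when
channels are dropped.

Training uses five rest windows (right edges -2 to -1 s, step 0.25 s)
and one intention window ($t = 0$, i.e. [-1, 0)) per trial; testing
slides over 17 windows from $t = -2$ to $0$ in 0.125 s steps. Features
are z-scored with statistics estimated on training windows only.

One caveat inherited from the offline design: the 0.1-1 Hz MRCP
filtering is zero-phase and applied to whole trials before windows are
cut, so causality holds at the level of window sample selection but not
of the filter itself. An online implementation would use causal filters
and should expect some performance drop.

## Sparse discriminant analysis

With 1056 features and at most ~300 training windows, classical LDA is
ill-posed. `fitSda()` performs sparse optimal scoring: the class
indicator scores are regressed on the features with an elastic-net
penalty, which selects features and fits the discriminant
simultaneously. The ridge part is fixed (default `gamma = 1e-2` on
normalized features — chosen by fixture behavior, kept explicit); the
lasso path (solved by glmnet on ridge-augmented data) is stopped at the
last solution with at most K nonzero coefficients. Ties at the K-th
entering feature resolve by path order, making fits deterministic. The
score/coefficient iteration runs to tolerance 1e-6 (at most 30 rounds),
though with two classes the optimal scores are unique up to sign and
the loop converges immediately. The budget default is $K = N - 2$ for
$N$ trials — the largest value below the per-fold training-trial count
$N - 1$. The intercept centers the two class-mean scores symmetrically
around 0, with higher scores meaning intention.

## Event-based evaluation

`looEvaluate()` runs trial-based leave-one-out: per fold, both OSFs,
the normalization and the SDA model are fitted on $N-1$ trials and the
held-out trial is scored on its 17 windows. All held-out scores are
pooled into a single event-based ROC: per trial, the rest event
(windows with $t \le -1$) is a false positive if any detection occurs
in it, and the intention event ($t \in (-1, 0]$) is a true positive if
at least one detection occurs. The window ending exactly at $t = -1$ is
counted as rest — its data lie wholly in the rest phase and it is a
rest exemplar in training; the alternative assignment is a
configuration away, since verbal definitions of "between -1 and 0" are
boundary-ambiguous. Pooling all folds into one ROC (rather than
averaging per-fold ROCs) was chosen because single held-out trials
yield degenerate one-point curves.

Two subtleties of event-based null behavior are worth knowing. First,
the evaluable grid has 9 rest-event windows but only 8 intention-event
windows, so even scores carrying no information give an event AUC of
8/17 (about 0.47), not exactly 0.5. Second, on data with *no* planted
effects the full pipeline scores systematically *below* that point:
the fold-fitted optimal spatial filters contrast the peri-onset window
against rest on the training trials, so under the null the classifier
partly learns a window-position artifact that does not generalize —
held-out late windows then look more rest-like than early ones. The
bias is conservative (the decoder under-reports intention on null
data, never invents it), and it disappears under the correct null
control for this design, label randomization: shuffling training
labels per fold yields pooled AUCs around 0.45 and the empirical
chance rate of correct trials near 21%.

The working point is the threshold with equal sensitivity and
specificity on the pooled ROC. A trial is *correct* when its rest event
is clean and an intention is detected in $(-1, 0]$; the anticipation of
a correct trial is the time of its first intention-interval detection
(negative, in seconds). `chanceLevel()` repeats the whole procedure
with training labels shuffled independently per fold (spatial filters
and normalization are label-independent and reused), 10 permutations by
default — a cost-driven default; the dispersion stabilizes quickly
because each permutation already averages over N folds.

# The synthetic generator

No public recordings accompany this problem, so the package ships a
generator (`generateRecording()`) whose defaults *are* the reference
study conditions: 50 self-initiated trials, 13 s apart, 32-channel
10/10 montage at 512 Hz. It plants:

* **Background**: independent 1/f Gaussian noise per channel
  (exponent 1, sd 14 uV).
* **Rhythms**: narrowband Gaussian processes (6.5-13 Hz and 14-26 Hz,
  sd 33 and 14 uV at the source) mixed through Gaussian scalp maps
  (sd 0.8 electrode spacings) centered on C3 and its mirror C4. The
  bands slightly overfill the 7-12/12-30 Hz analysis bands so every
  analysis bin carries rhythm.
* **ERD**: a multiplicative envelope on the lateralized rhythm source
  only, attenuating amplitude by $\sqrt{1 + d}$ from 1 s before onset
  to 1 s after (0.25 s raised-cosine transitions), so the planted
  band-power change is exactly $d$. The noise floor is untouched, which
  gives the percent-change metric a closed-form planted value.
* **MRCP**: a raised-cosine negativity (1.5 s rise) band-limited to
  0.1-1 Hz by iterating the measurement bandpass to its fixed-point
  shape, scaled so the typical per-onset minimum equals `mrcpPeak`, and
  mixed through a spatially centered (CAR-invariant) map with unit gain
  at Cz. These two constructions make the standard measurement chain
  (CAR, 64 Hz, 0.1-1 Hz, trial average) recover the planted peak
  rather than a filter-attenuated version of it.
* **Kinematics**: one rectified Gaussian burst (~0.5 s, sd 0.102 s)
  per trial whose 5%-of-maximum crossing falls within a few
  milliseconds of the true onset by construction.

Calibration choices were made once, from band-power arithmetic plus the
stated operating-range requirement, and then frozen. The ERD lead of
1 s keeps the planted attenuation out of the [-3, -1] baseline that
defines the ERD reference (a longer lead systematically compresses the
measured ERD% because the reference itself is depressed — a property
real experiments share). The noise level (14 uV) sets the overall
decoder difficulty so that leave-one-out accuracy on the defaults falls
in the 40-75% correct-trial range reported for healthy subjects in this
paradigm; no public SNR value exists for such recordings, so this is an
explicit calibration, not a measured quantity.

What the generator deliberately does *not* model: volume conduction
through a realistic head model (mixing is Gaussian-map shorthand),
blinks and EMG leakage (only an optional amplitude-outlier injector for
testing rejection), line noise (acquisition-side notch is assumed), and
non-stationarity across the session. Passing tests on this data
therefore demonstrate the correctness of the *pipeline machinery* and
its behavior under known ground truth — not performance on real EEG.

# Numerical choices and degenerate inputs

* All temporal filters are zero-phase Butterworth (orders: 4 for band
  power and ERD/OSF bands, 2 for the 0.1-1 Hz MRCP band); downsampling
  prefilters at 0.4 times the target rate.
* Morlet convolution uses full-trial reflection padding so the 1-2 Hz
  rows of a 6 s epoch are not dominated by edge transients. Even so,
  map cells within half a wavelet support of the trial edges (the cone
  of influence — about 0.7 s at 5 Hz) remain unreliable, and below
  ~10 Hz the percent-change cells are intrinsically noisy because a
  2 s baseline holds very few wavelet-independent samples; the
  operational 7-30 Hz feature range is unaffected.
* A zero-variance channel yields an all-zero AR spectrum rather than an
  error; zero-variance features are flagged and mapped to 0 by the
  normalizer.
* Constant decoder scores yield a flagged degenerate ROC with AUC 0.5.
* `snrDb` errors on zero-power noise epochs rather than returning
  infinities.
* Problem sizes in the test suite: planted-parameter recovery uses 200
  trials (where the sampling error of ERD% is ~2 points), decoder-level
  checks use the 50-trial reference condition, and driver-contract
  checks use 12 trials. These were chosen as the smallest sizes at
  which each quantity is stable.

# Known limitations

* GDF import is not implemented (EDF is; the internal store covers
  epoch-aligned data, which EDF cannot represent).
* The pipeline is strictly offline; no causal-filter mode exists yet.
* Repeated-measures group statistics across subjects/movements are out
  of scope; "subjects" in any group-style analysis here are seeded
  generator replicates.
* The montage is the fixed 32-electrode 10/10 set; other montages work
  for everything except the named-channel defaults (C3/Cz anchors,
  feature channel lists), which must then be supplied explicitly.
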