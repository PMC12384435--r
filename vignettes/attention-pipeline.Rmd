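---
title: "Decoding mental attention states from EEG: the attnstate pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding mental attention states from EEG: the attnstate pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sustained attention fluctuates over minutes: an operator drifts from focused
engagement through unfocused wakefulness into drowsiness. EEG is the only
practical modality with the temporal resolution to track this continuously,
but single-channel spectral features generalize poorly across sessions and
subjects. `attnstate` implements a hybrid feature-learning pipeline for
three-class attention decoding that combines channel-wise spectral features
with functional and effective connectivity between channels, a two-stage
feature-selection procedure, and an RBF-kernel SVM evaluated under
protocols of increasing strictness — including a temporally ordered,
non-shuffled split that guards against autocorrelation leakage.

Two montage configurations are supported end to end: a 7-channel
frontal/central/parietal layout (F3, Fz, F4, C3, Cz, C4, Pz) sampled at
128 Hz, and a dense 32-channel 10-10 layout at 500 Hz. A seeded synthetic
session generator emulates both, so every stage is testable without any
external recording.

## Pipeline stages and their models

### Preprocessing

Signals are band-pass filtered into the three wakefulness bands — theta
(4–8 Hz), alpha (8–12 Hz), beta (12–30 Hz) — with a zero-phase
forward–backward Butterworth filter (4th order per pass). Zero phase keeps
state annotations aligned with the filtered signal; the order is
configurable. Delta is excluded as sleep-dominant.

An ICA cleanup stage is available but is a no-op by default
(`reject_rule = "none"`): data are never silently altered. Opt-in rules
zero either the `k` highest-kurtosis components (blink/spike sources are
strongly leptokurtic) or a user-chosen index set before back-projection.

Segmentation cuts fixed windows (default 5 s) independently inside each
annotated state block, after dropping the block's first 4 s of
state-transition transients. The default step is 6 s — an overlap of
−1 s, i.e. a 1 s guard gap between consecutive windows; overlaps of 1 s
and 3 s are available through `segmentation_config(overlap_s = )`.
Windows never cross block boundaries, so labels are unambiguous. Per block
of duration $T$ the segment count is
$\lfloor (T - 4 - w)/s \rfloor + 1$.

### Connectivity (5 metrics × 3 bands)

Per segment and band, five pairwise metrics form the 15-matrix tensor:

* **PLV** $= \left| \frac{1}{N}\sum_n e^{i\,\Delta\phi(t_n)} \right|$,
  with phases from the FFT analytic signal of the band-filtered data.
* **PLI** $= \left| \frac{1}{N}\sum_n \mathrm{sign}\,
  \sin \Delta\phi(t_n) \right|$. The sign of the *wrapped* difference is
  taken as $\mathrm{sign}\sin\Delta\phi$, so exact zero-lag and antiphase
  differences contribute 0 — the property that makes PLI robust to volume
  conduction.
* **S index**: both series are delay-embedded ($d = 3$, $\tau = 1$,
  $k = 4$ by default, the common nonlinear-interdependence defaults); for
  each embedded point the mean squared distance to its own $k$ nearest
  neighbours is divided by the mean squared distance to the points at the
  *partner's* neighbour time indices, and the ratios are averaged.
  $S(X|X) = 1$ and $S \le 1$ always. Neighbour ties break towards the
  lower time index and a Theiler window of $\tau(d-1)$ samples excludes
  temporal self-matches.
* **GC** (pairwise Granger causality)
  $= \ln \mathrm{Var}(\varepsilon_{\text{restricted}})/
         \mathrm{Var}(\varepsilon_{\text{full}})$, where the restricted
  model regresses the target on its own $p$ lags and the full bivariate
  model adds the source's lags, both over the identical sample range so
  that nesting guarantees non-negativity.
* **PDC**: from the full $M$-channel MAR model of order $p$,
  $\bar{A}(f) = I - \sum_r A_r e^{-i 2\pi f r}$ and
  $\pi_{ij}(f) = |\bar{a}_{ij}(f)| / \sqrt{\bar{a}_j^H \bar{a}_j}$,
  averaged over 20 evenly spaced frequencies spanning the band. Column
  sums of squares are 1 at every frequency by construction.

The MAR order defaults to $p = 5$. GC is bivariate and PDC multivariate
because the GC definition is inherently pairwise while the PDC transfer
function is defined from the joint model. Directed matrices are stored as
`m[target, source]`, so GC *indegree* (total incoming flow into a channel)
is an off-diagonal row sum.

### Network profiling

Each of the 15 weighted matrices is thresholded at 130 linearly spaced
values in $[0,1]$ (values strictly above the threshold become undirected
edges after symmetrizing by the elementwise maximum). GC, the one
unbounded metric, is min–max rescaled per matrix first. At each threshold
a menu of scalar graph metrics is computed and each metric is aggregated
as its **sum** and **mean** across thresholds:

* 7-channel menu: global efficiency, local efficiency, mean clustering,
  mean degree, max degree → 10 descriptors per matrix (150 total);
* 32-channel menu: 17 scalars (adding degree variance, edge density,
  transitivity, component structure, assortativity, betweenness,
  closeness, eccentricity/diameter of the largest component, isolated
  count) plus the count of thresholds yielding a connected graph → 35 per
  matrix (525 total).

Both menus are configuration data, not code constants. The raw
(unthresholded) strict upper triangles contribute $M(M-1)/2$ local values
per matrix: 315 (7 ch) or 7440 (32 ch).

### Spectral features

Per channel, power spectrograms are computed per second with a Blackman
window of $M = 128$ samples,
$w(n) = 0.42 - 0.5\cos\frac{2\pi n}{M-1} + 0.08\cos\frac{4\pi n}{M-1}$,
averaged over the non-overlapping 1 s frames of the 5 s segment, floored
at $10^{-12}$ and converted to $10\log_{10}$ dB. Each channel contributes
exactly 80 bins: at 128 Hz the FFT is zero-padded to $2(80-1) = 158$
points so the one-sided spectrum has 80 bins; at 500 Hz the spectrum is
restricted to 0–40 Hz and linearly resampled to 80 bins so both montages
share one feature geometry. Both rules are package choices — nothing
forces 80 bins from a 128-point window — and are configurable
(`n_bins`, `freq_cap_hz`, `db_floor`).

First-order differences are taken over the *concatenated* spectral vector
(length $80C - 1$: 559 or 2559), each difference assigned to the channel
of its right-hand element; this concatenated reading is the only one
consistent with the totals above. A single temporal feature counts the
zero crossings of the difference signal, with zeros transparent: a
crossing is scored when the first nonzero sign after a run of zeros
opposes the sign before it.

### Assembly

Features are organized into $1 + 2C$ groups (all connectivity values; one
group per channel of raw spectra; one per channel of differences) and each
group is summarized by ten order-invariant statistics: lower/upper
quartile (linear interpolation), 10% two-sided trimmed mean, min, max,
standard deviation, mean square, moment skewness, excess kurtosis, and the
sum of square roots of absolute values (absolute because dB features are
routinely negative). Skewness and kurtosis are defined as 0 for
zero-variance groups to avoid NaNs.

The consolidated per-segment vector concatenates
`[spectra | differences | group statistics | zero-crossing |
graph descriptors | upper triangles]`:
$560 + 559 + 150 + 1 + 150 + 315 = 1735$ (7 ch) and
$2560 + 2559 + 650 + 1 + 525 + 7440 = 13{,}735$ (32 ch). The block order
itself is a serialization choice fixed by the layout registry; all block
sizes are forced by the construction.

An isolation forest (100 trees, subsample 256, contamination 0.02 when
enabled) can mask outlier training rows; it is fitted on training rows
only and its detector can score held-out rows without refitting.

### Two-stage selection

Stage 1 organizes the raw value blocks into $3 + 2C$ subsets (the
per-band connectivity triangles, the per-channel spectra, the per-channel
differences; 17 or 67 subsets) and projects each onto its two leading
linear discriminants. LDA is solved as the generalized eigenproblem
$S_w^{-1} S_b$ with a trace-scaled ridge ($10^{-6}\,\mathrm{tr}(S_w)/p$)
on the within-class scatter, because subsets can contain collinear
features. With three classes, two discriminants always exist.

Stage 2 concatenates the $2 \times$ subsets projections (34 or 134) with
the group statistics (150/650), the graph descriptors *excluding the
PLI-derived blocks* (120/420) — PLI profiles carry little inter-class
variance, and this exclusion is the only reading consistent with the
combined widths of 305 and 1205 — plus the zero-crossing feature. The
combined matrix is z-scored with training statistics (zero-variance
columns map to 0), pruned by a greedy left-to-right scan that drops any
column whose absolute Pearson correlation with an already-kept column
exceeds 0.9 (keep-first order makes the rule deterministic), and ranked
by a 100-tree random forest (`mtry = floor(sqrt(p))`, seed 34,
Gini importance, ties towards the lower index). The top 45 features feed
the classifier. Every fitted quantity — LDA bases, scaler, kept set,
ranking — is a function of training rows only; `apply_selection()` never
refits.

### Classification and protocols

An RBF-kernel SVM is tuned by stratified five-fold cross-validation over
$C \in \{0.1, 1, 10, 100\}$ and
$\gamma \in \{10^{-3}, 10^{-2}, 10^{-1}, 1, \text{scale}\}$ (with
"scale" $= 1/(p \cdot \mathrm{var}(X))$), ties resolved towards the
smaller $C$ then the smaller $\gamma$, and refitted on all training rows.
Five validation protocols are provided: per-subject random 80/20, pooled
random 80/20, leave-one-subject-out, leave-one-trial-out (one fold per
subject/session), and the temporal non-shuffled split: within each
subject and state stream the first 85% of samples in temporal order
train, and the first 17 test samples after the split point are discarded
as an autocorrelation buffer. Metrics are accuracy and macro-averaged
F1/recall/precision in percent (macro chosen as the class-balanced
convention; per-class values are also reported), with per-class F1
defined as 0 when precision + recall is 0.

## The synthetic generator

`generate_synthetic_session()` builds each state block as three
unit-variance band-limited oscillators (white noise band-limited exactly
in the frequency domain, so adjacent bands do not leak into each other)
scaled by a per-state amplitude profile, plus broadband white noise;
directed couplings are then applied as a stable VAR recursion whose
companion spectral radius is checked before generation. The default
profile follows classic attention physiology — state 0 beta-dominant
(focused), state 1 alpha-dominant (unfocused), state 2 theta-dominant
(drowsy) — with three consecutive 600 s blocks at 128 Hz over 7 channels,
and one centro-parietal coupling (Cz → Pz, lag 1, gain 0.5) active only
in the drowsy state, emulating the more distributed information flow of
low-vigilance states. Identical configurations, including the seed,
generate bitwise-identical samples.

What the generator does *not* emulate: volume conduction and reference
effects, non-stationarity within a state, 1/f background structure,
eye-blink and muscle artifacts (a blink-like spike train can be injected
manually for the ICA tests), and inter-subject variability. Passing tests
on synthetic sessions therefore demonstrate that the pipeline recovers
the structure it models — band-power contrasts and directed couplings —
not that real-data accuracies are reproduced.

## Numerical choices

* dB floor $10^{-12}$ on power before the log; no $-\infty$/NaN ever.
* Thresholding uses strict `>`; a weight exactly at a threshold is not an
  edge.
* The GC full-model residual variance is floored at $10^{-12}$ times the
  restricted variance, keeping GC finite in the noiseless limit.
* The MAR rank check uses a $10^{-12}$ QR tolerance: narrow-band
  multichannel regressors are ill-conditioned but not collinear, and only
  genuine rank deficiency (duplicated or constant channels) is an error.
* The S index evaluates, by default, at most 128 evenly spaced reference
  points per segment (neighbours still searched over all embedded
  points), making cost linear in segment length; short inputs use every
  point, so the estimator is exact there.
* LDA eigenvector signs are fixed (largest loading positive) for
  reproducibility.
* EDF output quantizes to 16 bits over each channel's range, as the
  format dictates; delimited and JSON-container formats are lossless and
  carry annotations, which plain EDF cannot.

## Problem sizes in the test-suite

The bundled tests run the full pipeline at desk scale: the shared
7-channel fixture uses three 52 s state blocks (24 segments), the
32-channel dimensional check uses three 27 s blocks (12 segments), and
the end-to-end decoding check runs five seeded sessions with three 67 s
blocks segmented at a 3 s overlap (90 segments each), asserting
intra-subject accuracy at least 30 points above the 33.3% three-class
chance level. These sizes are the package's choice of a fast, fully
reproducible demonstration; the generator defaults remain the 600 s
blocks described above.

## Known limitations

* The S index and pairwise GC are $O(M^2)$ per segment and band; dense
  montages are noticeably slower than the 7-channel configuration.
* The isolation forest and random forest are the only stochastic stages
  besides the splits; all take explicit seeds.
* The leave-one-trial-out protocol treats one session as one trial; finer
  trial structure must be encoded in `session` identifiers.
* ICA here is a compact FastICA; it is adequate for rejecting gross
  spike/blink components in the opt-in path, not a full artifact-removal
  suite.
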