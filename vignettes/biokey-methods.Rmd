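---
title: "Models and design choices in biokey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in biokey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biokey)
```

`biokey` implements two hybrid biometric matchers — a quantization sparse
matrix method (QSMI) over paired ECG/SpO2 sessions and a
multi-dimensional method (MDI) over multi-lead ECG — together with four
classical reference algorithms and a false-acceptance / false-rejection
evaluation harness. This vignette documents the models, the synthetic
data they are exercised on, and every numerical choice that was genuinely
open, so that results can be interpreted and the defaults revisited with
full context.

## The synthetic cohort: what it emulates and what it does not

The package ships no subject data. All experiments run on a generative
model with one parameter draw per individual
(`drawIndividualParams()`):

* **ECG morphology.** One cardiac cycle is a sum of five Gaussian bumps
  (P, Q, R, S, T), each with an amplitude, a width (s) and a center
  offset (s) relative to the R peak. Priors center on textbook adult
  values (R amplitude 1.0, T 0.32, P 0.13, Q −0.14, S −0.22; widths
  12–55 ms; P at −200 ms, T at +280 ms) with continuous log-normal
  amplitude/width jitter and Gaussian center jitter, so two individuals
  differ almost surely and the differences are of the size that
  distinguishes real subjects: relative wave proportions and timings,
  not gross shape. Distinct Gaussian bumps were chosen deliberately so
  that fiducial-point detection has a ground truth to be tested against;
  a morphology model without separable waves would make the waveform
  baseline untestable.
* **Heart rate** is uniform on 0.9–1.5 Hz (54–90 bpm) per individual and
  constant within a session.
* **SpO2** is a per-individual baseline, uniform on 94–99 %, plus a slow
  Gaussian random walk (step scale 0.10 % per √s) clipped to the
  physiological band [85, 100]. Nothing finer is modeled: the matcher
  only needs a slowly varying second channel whose level differs between
  individuals.
* **Sessions** share the individual's parameters and add fresh white
  noise (default standard deviation 0.05, i.e. 5 % of the nominal R
  amplitude) and a fresh SpO2 walk.
* **Multi-lead records** multiply one base morphology by per-lead gains
  drawn uniformly from 0.6–1.4, with independent per-lead noise — the
  simplest model in which leads are correlated but not identical.
* **Seeding.** Sub-seeds are derived from the master seed by fixed
  integer arithmetic per individual and session, so enlarging a cohort
  does not change the individuals already in it, and every function of
  the generator is a pure function of its arguments.

The default study design is 18 individuals with one enrollment and one
test session each; 30 s at 100 Hz for paired records and 10 s for
multi-lead records. Session length and sampling rate are conventional
wearable-sensor values chosen once, not estimates of any particular
dataset.

The generator deliberately omits baseline wander, electrode motion
artifacts, powerline interference, heart-rate variability within a
session, arrhythmic beats, and any real coupling between ECG and SpO2.
Passing tests therefore demonstrate that the algorithms work as
specified under their own assumptions — stable within-individual
morphology, distinct between-individual morphology — not that they reach
any particular accuracy on clinical recordings.

## QSMI

The pipeline is `mapToMatrix()` → `quantizeReduce()` → `cooEncode()` →
`qsmiSimilarity()`.

**Amplitude binning.** Counting requires integer indices, but ECG and
SpO2 amplitudes are continuous. The package bins by affine min–max
scaling to 1..n (round half up, clamped). Binning ranges are
configurable: a record's own min/max by default, or fixed ranges for
cross-session comparability. The enrollment path (`enrollQsmi()`) stores
each individual's training-session ranges and bins later probes with the
ranges of the template they are compared against, so a genuine probe
lands on its own grid. A constant channel (zero range) maps everything
to bin 1 with a warning rather than an error, since a flat SpO2 segment
is plausible data.

**Quantization.** The counting matrix is tiled into non-overlapping
m × m windows (stride = m, ragged edges zero-padded); each window sum,
plus the total of an optional non-negative bias mask, maps to a level
via thresholds a ≤ c ≤ d. The published threshold rule leaves the
interval between its first two cut points unassigned; the package closes
it by setting the second cut equal to the first (b := a), so the levels
partition the line — any window sum must receive some level. Defaults
are three levels with m = 2, a = 0, c = 2: a = 0 makes level 0 exactly
"empty window", and three levels is the configuration reported to
perform best in the source experiments, which never print their
thresholds; c = 2 was fixed a priori as the smallest cut that separates
"isolated visits" from "recurrent cells" in a 2 × 2 window. A four-level
spec defaults to d = 2c on the same reasoning.

**Matching.** Similarity is the Pearson correlation of the two reduced
matrices flattened over the full dense grid. Correlation over the COO
triples themselves would be undefined when supports differ, so the dense
flattening (zeros included) is used. If either flattening has zero
variance the similarity is defined as 0 with a warning. Thresholding
operates on the distance 1 − correlation so that one sweep convention
(accept iff score ≤ δ) serves all methods.

## MDI

**Mapping.** Coordinate values `round(s/R + Δθ)` are clamped to [1, u].
The published rule gives no rounding convention; round half up is used
because coordinates index a discrete grid. Defaults u = 32, window
m = 2, Δθ = 20 follow the best-reported 5-lead configuration
("Num_32_Red_2", Δθ = 20). R is not stated anywhere; the package default
R = 0.1 spreads the synthetic leads' dynamic range (≈ 2.5 amplitude
units across individuals and gains) over most of the 32-cell axis while
keeping session noise (sd 0.05) at about half a cell.

**Sparse element sequences.** Distinct occupied coordinates and their
occupancy counts v are kept in lexicographic coordinate order. DTW over
an unordered set is ill-defined, and a canonical order makes the
representation independent of time permutation and the text format
unambiguous; for that reason the container enforces lexicographic order
as an invariant and no time-of-first-occupancy ordering is offered.

**Distance.** Local cost is the squared Euclidean distance between
elements; sequences of equal length are compared by the direct aligned
sum (no warping), unequal lengths by the classic DTW recurrence with
D(0,0) = 0. The kernel is implemented in C++ (O(k·k′) time, O(k′)
memory).

Whether the occupancy v belongs in the local cost was genuinely open.
The package default is coordinates-only (`useValue = FALSE`), with the
occupancy-augmented cost behind a flag, because occupancies scale with
session length: with 1000-sample sessions single elements carry
v ≈ 200, one squared v difference dominates every coordinate term by
orders of magnitude, and whenever two sessions happen to produce
equal-length sequences the direct-alignment clause pairs large-v
elements with unrelated small-v ones and explodes genuine distances — in
cohort simulations this inverted the genuine/impostor ordering on 2 of
10 seeds, while the coordinates-only cost separated them on all 10 with
wide margins.

## Reference algorithms

* **RBP.** Successive differences are binarized (ties count as an
  increase), overlapping m-bit windows (stride 1, first bit most
  significant) become decimal words, and profiles are compared by the
  rank/frequency statistic. The word length is not stated for the
  original experiment; the default m = 4 keeps 16 possible words, enough
  to be discriminative at the session lengths used here, and is
  configurable. Rank ties break by ascending word value so ranking is
  deterministic, and ranks are always computed. Disjoint supports make
  the statistic's denominator zero; the distance is then defined as the
  maximal 1, with a warning.
* **Waveform features.** The only baseline with pre-processing: a
  zero-phase 0.5–40 Hz Butterworth band-pass, the conventional front end
  for fiducial extraction. R peaks are maxima above half the signal
  maximum with a 0.4 s refractory period; Q/S are the nearest minima
  within 80 ms, P/T the largest maxima in 300 ms pre-Q / 450 ms post-S
  windows, all scaled by the sampling rate. Beats without a strict
  P < Q < R < S < T ordering are dropped, and beats with coincident
  fiducials are skipped with a warning. The 19 features are averaged
  over beats; sessions are matched by Euclidean distance.
* **Wavelet pipeline.** R-R cycles are resampled to 284 points; the
  first 85 and last 43 points (128 total) frame the QRS; segments are
  grouped in fours. Which wavelet and which "four coefficients" form the
  vector is unspecified in the source; the package uses the 4-tap
  Daubechies filter (periodized, hand-implemented as no wavelet package
  is a dependency) at level 3, and takes each segment's level-3
  approximation coefficients as one block — four blocks of 16 per group,
  a 64-coefficient vector. Both the family depth and level are
  configurable; group vectors are averaged for matching.
* **Sparse-Euclidean baseline.** The printed form is a sum of squares
  and is the default; a square-root variant is available by flag. The
  source text scores baseline matches through "the correlation
  coefficient between two b's", which is undefined for scalars; the
  harness scores by the distance b directly.
* **PCA.** Rows of the stacked session vectors are centered, the
  covariance C = XXᵀ/n eigen-decomposed (via SVD of the centered matrix
  for stability; the eigen route is the independent oracle in the
  tests), and probes/templates are matched by Euclidean distance between
  their k = 5 projections — five components being the count reported to
  work well.

All five, plus QSMI and MDI, expose the same `fit(train)` /
`score(state, probe)` contract (`biometricMethod()`), so
`evaluateMethod()` runs any of them through an identical protocol.

## Evaluation protocol and numerical conventions

Enrollment uses the designated training session (default `"s1"`); every
remaining session is scored against every template (all-vs-all). FA is
the accepted fraction of impostor trials, FR the rejected fraction of
genuine trials, Acc = 1 − (FA+FR)/2 identically (an S4 validity
constraint, not a rounding convention).

`sweepThreshold()`'s documented default grid (0.001–0.030, step 0.001)
matches the published sweep, which is meaningful only on that study's
correlation-distance scale. The pipeline functions instead pass a
data-adaptive grid — midpoints between consecutive distinct scores plus
one point beyond each end (`scoreGrid()`) — which realizes every
achievable operating point of a score set regardless of the method's
score scale. Ties in the half-sum break toward the smallest threshold.
Display rounding is 2 decimals for percentages and 4 for rates; all
stored values are unrounded.

Other conventions: rounding is half-up wherever a continuous value meets
an integer grid (binning, coordinate mapping); MDI identification ties
break toward the first enrolled template, with a message; per-individual
FA excludes individuals with no impostor trials, with a warning.

## Problem sizes

The test suite runs cohorts of 2–18 individuals with sessions of 1–30 s
at 50–250 Hz; property suites use 100–200 random instances each (tiling
oracle, COO round trips, DTW vs exhaustive alignment enumeration at
lengths ≤ 5). The acceptance script uses the full default designs: the
18 × 2 paired cohort at 30 s / 100 Hz (324 trials) and the 10 × 2
five-lead cohort at 10 s / 100 Hz (100 trials). These sizes were chosen
as the package's standard benchmark configuration; everything scales to
larger cohorts through the same functions.

## Known limitations

* The synthetic generator's realism is bounded as described above;
  accuracies on it say nothing quantitative about clinical data.
* QSMI depends on amplitude ranges estimated from a single enrollment
  session; severe inter-session gain drift would degrade it unless fixed
  global ranges are supplied.
* The fiducial detector assumes an upright dominant R wave; inverted-QRS
  morphologies would need the threshold fraction adjusted.
* MDI cost grows as the product of sequence lengths; very fine reduction
  levels (small R) lengthen sequences and slow matching.
* The evaluation harness implements the half-sum criterion only — no
  ROC/EER machinery beyond the threshold sweep, and no significance
  testing.
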