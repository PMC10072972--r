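---
title: "Time-varying phase-lag-index connectivity of gait-aligned EEG"
author: "gaitpli authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying phase-lag-index connectivity of gait-aligned EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpli)
```

## The model

`gaitpli` estimates how the functional network of the cortex reorganizes
across the gait cycle. Its unit of analysis is a 2.5-s epoch of 32-channel
EEG aligned to the right-paw-contact (RC) event, sampled at 500 Hz after
preprocessing. The gait cycle is idealized as a 750-ms preparation phase
(left paw contact to right paw off, LC→RO) followed by three 250-ms walking
sub-phases (RO→RC, RC→LO, LO→LC); each cycle carries one of three terrain
conditions — flat-to-flat (FF), flat-to-unexpectedly-uneven (FU), and
uneven-back-to-flat (UF).

Connectivity is the phase-lag index. With `phi_x(t)` the angle of channel
`x`'s analytic signal, and the phase difference wrapped to (−π, π],

    PLI_xy = | mean_n sign( phi_x(t_n) − phi_y(t_n) ) |,  sign(0) = 0.

PLI is 0 when the phase difference is symmetric around 0 mod π — in
particular for identical signals and for zero-lag volume conduction, which
is why it is preferred over coherence for electrode arrays — and 1 when the
two channels are locked at any consistent nonzero lag. Some statements of
the estimator omit the absolute value while still requiring 0 ≤ PLI ≤ 1;
we take the absolute mean sign, the standard definition.

PLI is evaluated in 250-ms windows advanced in 125-ms steps (50% overlap):
a 2.5-s epoch yields 19 windows, a 750-ms preparation segment 5. The
analytic signal is computed once over the full epoch and then sliced into
windows; computing it per 125-sample window would put Hilbert edge
artifacts inside every window. With this grid the windows starting at
−250, 0 and +250 ms relative to RC coincide exactly with the three walking
sub-phases, and windows 1, 3 and 5 tile the preparation phase without
overlap; the preparation matrix is their element-wise mean. Intermediate
(straddling) windows contribute only to the time-resolved global-metric
curves, never to the phase matrices.

## Graph metrics

Each 32 × 32 PLI matrix is read as a weighted undirected graph. Following
Brain Connectivity Toolbox conventions, edge distances are inverse weights
(1/w, infinite for absent edges), shortest paths are Dijkstra's:

* **global efficiency** — mean of 1/d over ordered node pairs, 0 for
  disconnected pairs;
* **characteristic path length** — mean shortest-path distance over
  connected ordered pairs (the number of disconnected pairs is reported);
* **transitivity** — `sum_i 2 t_i / sum_i k_i (k_i − 1)` with `t_i` the
  Onnela triangle intensity (geometric means of max-normalized weights)
  and `k_i` the binary degree;
* **local** — strength (row sums), Onnela clustering, local efficiency
  (global efficiency of the node's weighted neighborhood subgraph), and
  eigenvector centrality (leading eigenvector by power iteration,
  tolerance 1e-10, returned non-negative with unit Euclidean norm).

Metrics are always computed on the full weighted matrix. The 50%-of-max
edge threshold (`thresholdEdges`) affects only exported edge lists and
visualizations; the threshold belongs to the network-display step, and
thresholding before computing weighted metrics would
conflate topology changes with weight changes.

Isolated nodes get strength, clustering and local efficiency 0 rather than
an error; an all-zero matrix gets eigenvector centrality 0.

## The synthetic generator

Matching recordings are rarely publicly available, so the generator is
the package's test bed and defines the study conditions. Each coupled
channel pair shares a narrow-band source

    s(t) = cos( 2π f (t − lag) + phi0 + d(t) ),

where `f` is the carrier (default 8 Hz), `lag` applies to the receiving
channel only (default a quarter carrier cycle, the PLI-maximal lag), and
`d(t)` is a Wiener phase drift shared by both copies, so the pair is
locked at a phase difference of exactly `2π f lag` regardless of drift.
Coupling strengths (condition × phase × pair, in [0, 1]) multiply the
source per sample according to the gait schedule, implementing
phase-dependent connectivity by linear mixing. Every channel additionally
receives a private background of three independently drifting tones with
carriers drawn from 4–30 Hz, plus white Gaussian noise.

Two numerical choices matter and were fixed by Monte-Carlo calibration
before the pipeline was assembled:

* **Drift smoothness.** The drift is a Wiener process on a 25-Hz knot grid,
  linearly interpolated. Sample-scale Wiener increments would exceed the
  carrier advance per sample, making the instantaneous frequency change
  sign and the analytic-signal phase an unfaithful estimate of the
  generative phase, which breaks even a shared-source pair's apparent
  lock. Coarse knots bound the drift slope well below the carrier.
* **Null level.** The default drift SD (3.5 rad/√s) and the spread of
  background carriers make the phase difference of uncoupled channels
  sweep several cycles per window, driving their PLI down to ~0.15–0.3.
  The estimator itself has a positive floor here: with 125 samples per
  window, the sign of the phase difference is autocorrelated on the
  timescale of the inverse analysis bandwidth, so only a few dozen
  effectively independent signs enter each mean — the null is biased away
  from zero for any signal in this band. Recovery checks therefore test
  the coupled-vs-uncoupled *margin* (≥ 0.2) and the Spearman rank
  agreement between generative coupling and estimated phase-collapsed PLI
  (> 0.8), both of which the test suite and the acceptance script compute,
  rather than an absolute null of zero.

The default coupling profiles emulate the qualitative physiology of the
task: strong bilateral-motor and motor–retrosplenial coupling during
preparation in every condition, sustained right-motor–retrosplenial
coupling during the right-limb swing, a left-somatosensory burst after
unexpected contact with uneven terrain (FU, RC→LO), and globally weakened
coupling when the upcoming terrain is predictable (UF, late phases). No
amplitude or SNR statistics are available for such recordings; the
default noise SD (0.15 against unit-order signal amplitudes, SNR ≈ 20) is
a choice, not a calibration. What passing tests show is that the pipeline
recovers phase- and condition-dependent coupling from signals with these
statistics; real EEG adds nonstationarity, 1/f broadband structure,
artifacts and volume conduction that the generator deliberately omits
(zero-lag common sources are, however, exactly what PLI discounts).

Gait schedules use the idealized 750/250/250/250-ms durations with
optional uniform jitter (default 0), since the analysis itself
standardizes phase durations; condition labels follow a caller-given
sequence or a balanced shuffled draw.

## Preprocessing choices

The filter chain is a 2nd-order IIR notch (RBJ biquad, quality factor 30)
at 50 Hz followed by a 4th-order Butterworth band-pass at 3–50 Hz, both
applied forward–backward for zero phase — any phase distortion would bias
the PLI directly. The protocol fixes the stages and their order
(notch → band-pass → common average → downsample to 500 Hz); the filter
designs themselves are ours and follow standard EEG practice. Downsampling is plain
decimation, alias-free because the pass band ends at 50 Hz ≪ 250 Hz.
Independent-component cleaning of real recordings is inherently manual and
is represented by a pluggable no-op hook (`applyCleaner`). Epochs are the
half-open window [RC − 1 s, RC + 1.5 s) snapped to the nearest sample;
epochs overlapping the recording edges are skipped and counted.

## Statistics and classification

Condition effects on each metric (per phase, global and per brain region)
use classic one-way fixed-effects ANOVA (`stats::oneway.test`, equal
variances) with Tukey HSD post hoc pairs (`stats::TukeyHSD`); the choice
of post hoc procedure is open, and Tukey is the standard companion for
three groups. P values are
per-comparison and deliberately uncorrected across metrics and phases,
as flagged in the output. Animal identity is not modeled (epochs pooled).

Classifier settings are fixed as: SVM with RBF kernel, cost 1, gamma = 1/(dim · var); Gaussian naive Bayes;
KNN with k = 5, Euclidean distance. Features are standardized with
training-fold statistics only; features with zero training-fold variance
(e.g. the structural zeros of a flattened PLI diagonal) are dropped within
that fold. F1 is macro-averaged over the three classes (the binary
harmonic-mean formula applied per class). Folds are stratified, derived solely
from the label vector and the seed, so every feature family is compared on
identical splits.

## Problem sizes and numerical notes

The test-suite and acceptance runs simulate at 500 Hz with 6–15 epochs per
condition (the package's chosen demonstration scale; the estimator and the
tensor shapes are identical at any scale — only per-condition averages get
noisier as n shrinks). Degenerate inputs are defined, not exceptional:
ANOVA on groups with equal means and zero variance returns F = 0 with a
warning; conditions with zero epochs are omitted from averages with a
warning; disconnected graphs report path length over connected pairs and
the disconnected-pair count. Ties at the exact threshold weight are
removed by `thresholdEdges` (strictly-greater survives). The phase wrap
maps boundary values to +π so the signum never sees −π and +π as distinct
outcomes for the same geometric angle.

## Limitations

Single broad 3–50 Hz band (no band-wise decomposition); no artifact
simulation beyond white noise and an optional 50 Hz tone; no 3-D
anatomical rendering; no mixed-effects modeling of animal identity; EDF
input is not supported (delimited text only). Full-scale real-data
classification accuracies for this assay come from nearly two thousand
epochs and are not reproducible from synthetic data at demonstration
scale; the package's
classification checks are sanity and trend checks (separable features
classify at ceiling, permuted labels at chance, merging gait phases never
hurts on phase-differentiated data).
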