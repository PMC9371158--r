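---
title: "Explaining 1D convolutional activity-recognition models with grad-CAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining 1D convolutional activity-recognition models with grad-CAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(harcam)
```

## The problem

Convolutional classifiers of wearable accelerometer windows report excellent
validation numbers and still fail in the field. Two failure modes dominate.
First, when the same subjects appear in training and validation
(subject-dependent, SD, evaluation), the network can recognize *who* is
moving rather than *what* they are doing, because every activity window
carries the subject's personal movement signature; held-out-subject
(subject-independent, SI) evaluation then collapses. Second, acquisition and
windowing faults leave physically implausible artifacts in the data —
one-sample level jumps of ~11 m/s², i.e. a change no human can produce in
0.02 s at 50 Hz — and the network learns to fire on the artifact rather
than the movement.

`harcam` packages the complete audit loop for these failure modes: a data
model for fixed-length tri-axial windows, a synthetic cohort generator, SD /
SI / per-activity biometric (BUI) splits, trainable 1D CNNs with exact
gradient access, 1D grad-CAM saliency, and the audit statistics (importance
extent, discontinuity detection with heatmap co-localization, HAR-vs-BUI
performance correlation, SD−SI gap flags).

## The saliency method

For a window of length $N$ and a class $c$, let $A^k_i$ be the activation of
filter $k$ at temporal position $i$ of the last convolutional layer (length
$Z$), and $y^c$ the pre-softmax class score. The importance weight of each
filter pools the backpropagated gradient over time only:

$$\alpha^c_k = \frac{1}{Z} \sum_{i=1}^{Z} \frac{\partial y^c}{\partial A^k_i}$$

The raw map is the linear combination $m_i = \sum_k \alpha^c_k A^k_i$ with
**no ReLU**: for biosignals, strongly negative contributions are evidence
too, and clipping them hides structure. The map is then min–max normalized
to $[0,1]$ and stretched to the input length with **nearest-neighbour**
interpolation, $L^c_j = \tilde m_{\lfloor jZ/N \rfloor}$, which renders
constant-importance bands rather than the misleadingly smooth gradients of
linear interpolation. Normalizing before or after this interpolation is
equivalent because nearest-neighbour introduces no new values. A constant
raw map (e.g. from a zero-weight class head) normalizes to all zeros, so "no
signal" reads as "no importance". `explain()` implements the pipeline;
`activations_and_gradient()` exposes $A$ and $\partial y^c/\partial A$, and
the test suite verifies the gradients against central finite differences at
relative tolerance $10^{-4}$.

The ReLU-on-the-combination variant of the original image formulation is
available via `explain(..., relu = TRUE)`; $y^c$ defaults to the pre-softmax
score, with `post_softmax = TRUE` as the alternative reading.

## Architectures and training

`build_architecture()` declares the two reference networks. Both stack
convolutional blocks of two length-preserving ("same"-padded) convolutions
with 100 feature maps and ReLU; max-pooling (size 2, stride 2, ceiling mode)
follows all blocks but the last; a 0.5-dropout layer and a softmax head
close the network. CNN1 uses 4 blocks with kernel 8 and pools after blocks
1–3; CNN2 uses 3 blocks with kernel 4 and pools after blocks 1–2. For a
151-sample window the final convolutional layers therefore see 19 and 38
temporal positions respectively (151 → 76 → 38 → 19 under ceiling halving) —
these two resolutions pin down the only padding/pooling arrangement
consistent with the declared behaviour, which is why the package adopts it.
The pooling placement and the single dropout between the last block and the
head are the simplest arrangement reproducing those resolutions.

Training (`train_model()`) minimizes categorical cross-entropy with Adam
(default hyperparameters, learning rate $10^{-3}$); the protocol defaults
are 300 epochs with batch size 256, and after every epoch the validation
**macro F1** is recorded, with the best epoch's parameters checkpointed
(earliest epoch on ties). Windows are fed raw by default — gravity included
— because that is what the deployed pipeline sees; per-channel
standardization with training-set statistics is available via
`train_config(standardize = TRUE)` and is used in the package's own audit
experiments, where it markedly sharpens saliency (the ±9.81 m/s² gravity
offset otherwise drives about half of all first-layer ReLU features
everywhere and pads the heatmap with a high baseline).

The network engine is implemented in-package (batched im2col gathers feeding
BLAS matrix products, with exact backpropagation through every layer); this
is what makes the designated-layer gradient contract checkable against
finite differences rather than an opaque framework internal.

## Splits

`split_subject_dependent()` is an unstratified seeded hold-out
(default 70/30, seed 42) using an explicitly implemented Fisher–Yates
shuffle, so the permutation rule is part of the package contract; the
validation count is `round(val_fraction * n)` with ties-to-even (the
rounding direction is not externally constrained, so the package documents
this choice). `split_subject_independent()` routes windows by subject
(default: subjects 1–9 held out, 30% of a 30-subject roster) and involves no
randomness. `make_bui_subsets()` filters the dataset per activity and
re-applies the SD semantics inside each subset with the subject as target;
activities with fewer than 2 windows or a single subject are skipped with a
reason code.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without any
external download. It emulates the structure of peak-centred smartphone
benchmarks: 151-sample, 3-axis windows at 50 Hz (3 s with inclusive
endpoints); 17 default activities (9 ADLs, 8 falls) with the benchmark's
class imbalance and missing subject–activity pairs; gravity as a constant
≈9.81 m/s² on a rotated axis; and a key event at the central timestep
(index 75, 0-based), mirroring peak-triggered windowing.

Three nested sources of individual variation are generated, all scaling
*linearly* with `signature_strength` (so strength 0 makes the cohort
generatively homogeneous):

* **subject signatures** — gait-frequency offset (sd 0.2 Hz at full
  strength), per-axis gains in [0.5, 1.5], harmonic content, smoothing
  width, and a device-orientation rotation (up to 25°);
* **performance styles** — per *(subject, activity)* pair: amplitude factor,
  harmonic amplitude and phase jitter, secondary-axis phases, and
  envelope width. A style is shared by all windows of its pair: it encodes
  *how this person performs this activity*, which a subject-dependent model
  can memorize but a subject-independent model never observes. This is the
  generative stand-in for the personal information that biometric
  identification exploits;
* **white noise** per sample (`noise_sd`, default 0.4 m/s²).

The signature and style ranges are engineering choices — no quantitative
inter-subject variability is externally specified — set so that personal
information is strong at full strength, consistent with near-perfect
biometric identification being achievable on such data. They must not be
read as estimates of any real cohort.

`inject_discontinuities()` plants the artifact model: at a uniformly drawn
interior timestep the signal jumps by exactly ±`jump_magnitude` between two
consecutive samples and (in the default sustained-step mode) stays at the
shifted level to the window end, the way a segment merged from a different
trial sits at a foreign level. The jump direction moves the signal toward
the opposite side of the axis range (a rise from about −10 to +1, or a fall
from +3 to −9), so the landing level remains physically plausible and only
the one-sample edge is anomalous. `position_granularity =
"subject-activity"` reuses one position per (subject, activity) pair,
emulating recording-level faults that recur across the windows cut from one
recording. The injector returns the ground-truth plant list, which the audit
tests use as an oracle.

## The audit

`run_audit()` combines four statistics:

* **Importance extent** — the fraction of timesteps with heatmap value
  ≥ τ (default 0.7, the threshold used when reading regions of importance
  off the figures). It formalizes "how much of the signal the model looks
  at" and is monotone non-increasing in τ.
* **Discontinuity events** — every one-sample difference above
  `jump_threshold` (default 10 m/s²: the printed artifact jumps of ≈11.3 and
  ≈12.0 m/s² exceed it, while smooth motion at 50 Hz stays far below; a 2 Hz,
  5 m/s² sinusoid's steepest one-sample step is ≈1.26 m/s²).
* **Co-localization** — for a window with events, the share of
  super-threshold heatmap timesteps inside a ±w halo around the events
  (w = 2, plus the two samples forming the jump), compared against the
  halo's coverage fraction; `enrichment = score / chance` is 1 in
  expectation for unlocalized importance (property-tested under a random
  null).
* **SD−SI gaps and flags** — per-class recall (TPR) difference between the
  SD and SI models on their validation sets; a class is flagged as
  bias-suspect when the gap exceeds `gap_threshold` (default 0.20, the
  order of the published gaps) **and** discontinuity events are present in
  that class. Conjoining performance and physical evidence keeps ordinary
  generalization gaps from being misread as data faults.
* **HAR–BUI correlation** — Pearson correlation (with the
  `t = r\sqrt{(n-2)/(1-r^2)}` noncorrelation p-value, via `cor.test`)
  between per-activity HAR-SD scores and per-activity biometric
  identification scores; macro-F1 pairing by default, accuracy by flag,
  since either pairing is consistent with the published (r, p) pairs.

## Desk-scale study designs used by the package's own tests

The test suite trains small custom specs (2 blocks × 2 convolutions, 16–24
filters, kernel 8) for 15–40 epochs at batch 64 on cohorts of ~300–1100
windows, with per-channel standardization. These sizes keep the whole suite
within desk-scale minutes while leaving the phenomena expressible; the
protocol-faithful 100-filter/300-epoch settings remain the documented
defaults.

* **SD-vs-SI gap**: six subjects, two distinct periodic classes plus four
  classes sharing one quiet template whose identity is carried by
  performance styles. SD macro F1 exceeds SI macro F1 by ≈0.1–0.2.
* **Bias localization**: eight subjects; four distinct classes plus a quiet
  identical quartet into which sustained steps (magnitude 11 m/s²,
  probability 0.8, y and z axes) are planted. The audit then measures
  co-localization enrichment of the SD model's saliency at the planted
  edges and flags classes by the gap-and-events rule.

Development of these designs surfaced two mechanisms worth recording.
First, when artifact positions are shared per (subject, activity) pair, a
flatten-head network position-codes the artifact; the globally pooled
$\alpha_k$ of edge-sensitive filters then averages positive own-class and
negative other-class weights and often lands *negative*, so min–max
normalization maps the very edge the network exploits to ≈0. Uniform
per-window positions keep edge evidence position-robust and its pooled
gradient positive. Second, a subject-independent network faced with an
identical-template group "dumps" ambiguous windows onto one or two favorite
classes; those favorites then show high SI recall, which makes *every*
planted class simultaneously exceeding a fixed 0.20 recall gap a fragile
event at this scale — consistent with the published experience, where only
three of the four artifact-affected ADLs showed gaps above 20%.

## What passing tests do and do not show

The generator produces stylized harmonic motion with ideal labels, exactly
centred events, stationary noise and exactly planted artifacts. Passing the
audit on synthetic cohorts demonstrates that the machinery — gradients,
saliency, splits, statistics, flags — is correct and that the qualitative
phenomena (SD inflation from personal signatures; saliency drawn to
implausible edges) are reproducible under controlled conditions. It does not
certify behaviour on real recordings, where inter-subject variability,
sensor placement, drift and label noise are richer; the importance-extent
ordering across BUI/SD/SI strategies, in particular, is a tendency reported
at full scale (100 filters, 300 epochs) that the package's desk-scale
training does not reliably reproduce, so the suite measures extents but does
not assert that ordering.

## Numerical choices and degenerate inputs

* Validation-size rounding: nearest, ties to even; at least 1 and at most
  n−1 windows in validation.
* Prediction ties resolve to the lowest class index.
* Max-pool ties take the earlier position; odd lengths are padded with −∞
  (ceiling mode).
* Zero-denominator precision/recall/F1 return 0 with an `undefined` flag so
  macro means stay defined.
* Constant raw heatmaps normalize to zeros; co-localization with no events
  or no super-threshold timesteps is reported as undefined, not thrown.
* The nearest-neighbour index rule is `floor(j * L / N)` exactly, avoiding
  platform-dependent rounding of half-integers.
* All stochastic operations take explicit integer seeds and restore the
  caller's RNG state; generation, injection and training are bit-reproducible
  per seed within one R build.

## Limitations

The engine is CPU-bound R + BLAS: protocol-scale runs (11k windows, 100
filters, 300 epochs) are possible but slow; the package targets audit-scale
experiments, not leaderboard training. Heatmaps are shared across the three
axes (feature maps mix axes after the first convolution); per-axis
attribution is out of scope. The archive adapter for external benchmark
downloads is best-effort and must be verified against the actual archive
layout.
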