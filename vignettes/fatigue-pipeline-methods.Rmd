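---
title: "Methods: video-free EEG fatigue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-free EEG fatigue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fatigueEEG)
```

## The problem and the model

Watchkeeping operators (the motivating case is ship deck officers) accumulate
fatigue over long, monotonous duty periods, and fatigue is a leading
contributor to human-error accidents. This package implements a video-free
pipeline that classifies an operator's state into three levels — 1 = alert,
2 = middle, 3 = fatigue — from four EEG channels: FP1, FP2 and FZ on the
non-hair-bearing forehead (practical for dry electrodes) and O2 over the
right visual cortex, sampled at 500 Hz.

The pipeline has five stages.

1. **Preprocessing.** Each channel is band-pass filtered to 1–40 Hz
   (zero-phase, so channels stay time-aligned) and cut into non-overlapping
   1.8 s epochs; each epoch is mean-subtracted. A 180 s state section
   therefore yields exactly 100 epochs per channel.

2. **Ground truth from reaction times.** The operator's reaction time (RT)
   to periodic rudder orders is the fatigue proxy. Pooled RTs are clustered
   on the 1-D RT axis with k-means (k = 3) and clusters are relabeled by
   ascending center. For each subject, the 180 s EEG sections around the
   orders with the minimum, median and maximum RT become the alert, middle
   and fatigue sections. In the reference conditions the three RT regimes
   are 0.8–1.4 s (alert), 1.4–1.9 s (middle) and 1.9–2.5 s (fatigue), and an
   RT above 2.2 s raises a "relieve the watch" flag.

3. **Eyelid closure from occipital alpha.** The classical video statistic
   PERCLOS needs a camera; instead, the eyelid closure degree (ECD) is
   estimated from EEG. Per O2 epoch, a Hamming taper is applied, squared FFT
   magnitudes are summed over theta (4–8 Hz), alpha (8–13 Hz) and beta
   (13–30 Hz), and the alpha share is
   Per(α) = 100 · Pα / (Pθ + Pα + Pβ). The closure estimate is the published
   linear model eECD = −31.37 + 1.56 · Per(α) (fit elsewhere against
   eye-tracking ground truth, R² = 0.904; this package does not refit it —
   only its arithmetic is testable here). Raw values can be negative; they
   are min–max normalized to [0, 1] per subject and session, because the
   model's offset error is subject-specific.

4. **Wavelet features and fusion.** Each frontal-channel epoch is decomposed
   by a five-level db5 discrete wavelet transform into details D1–D5 and
   approximation A5 (at 500 Hz, D5 spans 7.8–15.6 Hz and carries alpha; A5
   spans 0–7.8 Hz). Per sub-signal the mean absolute value, sample standard
   deviation and root mean square are computed, plus the Shannon
   wavelet-energy entropy of D1 only — 19 features, ordered A1..A4, B1..F3
   (A = D1 … F = A5; within a letter 1 = MAV, 2 = SD, 3 = RMS; A4 = SE(D1)).
   The subject's normalized eECD for the sample is replicated onto the three
   channel rows, giving 20-value fused rows.

5. **Classification and vote.** Rows are z-scored with statistics fit on
   training subjects only, then classified by a bidirectional GRU (GRU,
   LSTM, Bi-LSTM, SVM, k-NN and random-forest alternatives are provided)
   under subject-wise 7-fold cross-validation (21 subjects → 18 train : 3
   test per fold). Each sample's three channel predictions are corrected by
   majority vote: 2-of-3 agreement wins, three-way disagreement yields the
   explicit code 0 and scores as wrong.

## Numerical and design choices

**Wavelet boundary handling.** The Mallat cascade uses *periodization*:
the epoch is treated as circular (odd lengths duplicate the last sample
first). For the orthonormal db5 filters this makes the transform an
orthogonal change of basis — reconstruction is exact to rounding, and
subband energies sum to the signal energy exactly whenever every level has
even length (length divisible by 2^5). Symmetric half-point extension was
considered and rejected: it inflates total coefficient energy by ~5% on
1.8 s epochs, which breaks energy accounting between subbands. The filter
taps are hard-coded and the coefficients are cross-checked in the tests
against frozen values from an independent DWT implementation.

**Entropy probabilities.** The Shannon entropy's p(x_i) is taken as the
normalized squared coefficient x_i²/Σx_j² (wavelet-energy entropy), chosen
over histogram binning because it is bin-free and invariant to signal
scale.

**Band-power bin convention.** An FFT bin belongs to a band if
low ≤ f < high (half-open), so adjacent rhythm bands never double-count:
8 Hz belongs to alpha, 13 Hz to beta.

**Filters.** The recording-level 1–40 Hz filter is a zero-phase cascade of
an order-2 Butterworth high-pass and an order-6 Butterworth low-pass (each
applied forward-backward). The asymmetric orders are deliberate: a gentle
high-pass avoids numerical fragility at 1 Hz/500 Hz normalized frequency
while still removing drift and DC, and the steep low-pass attenuates 50 Hz
mains by more than 20 dB. The theta/alpha/beta split uses order-4
band-passes, which cleanly isolate pure tones in their own band.

**Recurrent input layout.** Per-channel-row prediction rules out
cross-epoch sequences, and a length-1 sequence would make recurrence
vacuous, so each 20-value fused row is fed as a length-20 sequence of
scalar inputs (one feature per timestep). The per-position hidden states
(both directions concatenated for bidirectional models) are mean-pooled,
passed through dropout (0.2) and a 3-unit softmax layer, and trained with
Adam at the reference learning rate 0.005. "Minimum training step size
600" is read as a floor on optimizer steps: training runs up to
`max_epochs` epochs, continuing past it if fewer than `min_steps`
minibatch steps have occurred. The cells, backpropagation-through-time
and Adam are implemented in plain matrix algebra; gradients are validated
against central finite differences, and the GRU step against an
independent elementwise evaluation of the gating equations, in the test
suite.

**k-means details.** `stats::kmeans` with 50 random restarts; for this
well-separated 1-D problem the global optimum is reached with near
certainty, so dedicated seeding schemes are unnecessary. Clusters are
relabeled by ascending center, which makes labels invariant to
initialization; decision boundaries are midpoints between adjacent
centers. Ties on the minimum/maximum RT resolve to the earliest order;
even counts use the lower median. Clustering is pooled across subjects.

**Degenerate inputs.** A zero epoch has zero band power (closure
estimation refuses it); an all-zero D1 sub-signal gets entropy 0 with a
warning; a zero-variance feature column is left unscaled with a warning; a
constant eECD series normalizes to 0.5.

## What the synthetic cohort emulates

The reference recordings (21 subjects) are not publicly deposited, so the
package ships a seeded generator that reproduces the *statistical
structure* the pipeline assumes, making every stage testable end to end:

- three 180 s state sections per subject at 500 Hz over FP1/FP2/FZ/O2;
- rhythms as band-limited Gaussian noise whose occipital alpha share of
  theta+alpha+beta power rises 25% → 40% → 55% across states (the alpha
  component is calibrated against the pipeline's own Hamming-FFT
  estimator, since spectral leakage otherwise biases the realized share
  toward the middle; realized values land within ~2 points of target);
- frontal channels carry a weaker copy of the alpha effect (80% of the
  occipital state contrast on the alpha *fraction*) plus two further
  drowsiness signatures with well-documented real-EEG analogues: the theta
  share of non-alpha power rises 0.55/0.65/0.75 and overall frontal rhythm
  amplitude grows by 0%/12%/25% across states. Effect sizes were set once
  so that the relative structure of the emulated study is preserved —
  frontal EEG features alone support strong but imperfect row-level
  classification, the fused closure feature adds a small increment, and
  the channel vote adds a few points on top;
- per-subject individual differences: log-normal jitters (~8%) on overall
  amplitude and on the theta/beta balance;
- 10 rudder orders per section (21 × 30 = 630 RT records), with RT values
  drawn Beta(3,3)-scaled inside the printed per-state regimes. The regimes
  touch at 1.4 s and 1.9 s; mid-regime concentration (visible as separated
  clusters in the reference RT scatter) is required for k-means to recover
  memberships at the ≥99% level — wall-to-wall uniform draws would leave
  ~4% of points on the wrong side of the equilibrium boundaries;
- the state-defining orders (minimum RT, pooled lower-median RT, maximum
  RT) sit at their sections' centers, emulating sections that were cut
  from a longer session around exactly those orders, so the min/median/max
  selection recovers the generated sections.

The generator is deliberately *not* physiological EEG: no 1/f background,
eye blinks, electrode artifacts, or non-stationarity within a section.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that its statistical assumptions suffice for recovery — they
do not validate the published accuracy figures on real recordings, which
are documented here as non-reproducible context (fused Bi-GRU 90.19%,
+1.89 points over EEG-only, 95.74% after voting).

## Problem sizes used by the checks

The package's own evaluation runs the full default cohort — 21 subjects,
180 s sections, 18,900 fused rows — with a reduced recurrent
configuration chosen for a single-CPU run: 48 hidden units, minibatch 64,
at most 6 epochs with at least 1,200 optimizer steps, and one held-out
3-subject fold per master seed, averaged over 3 master seeds. The full
reference configuration (128 units, up to 30 epochs) is the package
default for real use. Unit tests use miniature cohorts (3 subjects, 36 s
sections) whose structure is identical.

## Known limitations

- Ocular-artifact removal is out of scope: the band-pass stands in for the
  reference preprocessing chain's artifact-subspace steps, and the
  synthetic data contain no ocular artifacts. On real recordings this is a
  fidelity gap.
- The closure model's absolute accuracy is unverifiable without
  eye-tracking ground truth; only its arithmetic and monotonicity are
  tested.
- Whether Per(α) should average several sub-windows per epoch is not
  settled; one Hamming window per 1.8 s epoch is used.
- Baseline classifiers consume the same 20-value per-channel rows as the
  recurrent models (not flattened 60-value samples).
- k-NN distance ties are resolved by a seeded draw rather than a
  smallest-index rule.
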