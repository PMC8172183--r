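---
title: "Methods: biomarkers, latent representations and the classification protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarkers, latent representations and the classification protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Laboratory stress protocols in the Trier Social Stress Test (TSST) family
expose a participant to four conditions of increasing demand: a resting
baseline, a speech-preparation task, public speaking, and mental arithmetic.
The analysis question is whether scalp EEG recorded at the three midline
channels Fz, Cz and Pz carries enough information to classify *which* of the
four conditions a one-second window of signal came from — a four-class
problem, much harder than the binary stressed-vs-rest question most spectral
biomarkers were validated on.

`eegstress` implements this analysis end to end: a seeded synthetic EEG
generator that emulates the TSST recording protocol, signal conditioning,
three spectral biomarker feature sets, a from-scratch autoencoder whose
latent code is used as an alternative feature representation, a
multi-classifier benchmark under stratified 5-fold cross-validation, and
t-SNE diagnostics.

## The synthetic generator

No public recordings accompany this protocol, so the package ships a
generator whose defaults *are* the study conditions: 600 s baseline, 600 s
preparation, 300 s speech, 300 s arithmetic, sampled at 250 Hz (optionally
1000 Hz to exercise the resampling path). Each channel is a sum of four
band-limited Gaussian-noise components — theta 4–7 Hz, alpha 7–13 Hz, beta
13–39 Hz, gamma 25–45 Hz, produced by forward–backward Butterworth band-pass
filtering of white noise — over a `1/f` pink-noise background plus white
noise. Base band amplitudes (RMS 3, 4, 2, 1 µV for theta, alpha, beta, gamma;
pink 4 µV, white 1 µV) keep total RMS near 7 µV, inside the plausible 5–50 µV
scalp range.

Stress is injected the way the workload literature describes it: relative to
baseline, a condition with intensity coefficient $c$ multiplies the Fz theta
gain and the all-channel gamma gain by $1 + c \cdot s$ and divides the Pz
alpha gain by the same factor, where $s$ is the user-facing
`stress_strength`. The coefficients ($c = 0.15$ preparation, $0.30$
arithmetic, $0.50$ speech) are monotone in assumed task demand, making the
expected brain-load index and relative gamma orderings controllable in closed
form from the gain products. No published effect size exists for these
between-condition spectral contrasts, so `stress_strength` is an explicit
knob, not an estimate; $s = 1$ is the package's default study condition.
Inter-subject variability is multiplicative log-normal jitter (sd 0.1 on the
log scale) on every channel-by-band gain, drawn once per subject so
within-subject condition contrasts are preserved; the multiplicative form
keeps powers positive.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: ocular and muscle artifacts, non-stationarity
within a task, volume conduction between channels (channels are independent
draws), event-related structure, and circadian or session effects. Real-data
accuracies will be lower, and the artifact-cleaning stages real recordings
need (ASR, ICA-based component rejection) are deliberately out of scope:
synthetic signals are clean by construction. An amplitude-threshold window
rejection hook (`reject_windows()`) is provided but disabled by default.

Note one deliberate consequence of the gain design: because a stress
condition raises Fz theta *and* gamma together, the relative gamma at Fz
specifically can fall slightly even as RG at Cz and Pz and the feature-set
mean rise. Monotonicity claims in the tests are therefore stated on the BLI
and on mean RG, which the analytic gain products do order.

## Signal conditioning

Raw recordings pass a 1 Hz high-pass and a 50 Hz low-pass IIR filter, then
are downsampled to 250 Hz. "IIR" leaves the family open; the package uses
4th-order Butterworth sections applied forward–backward (zero phase), the
conventional choice in EEG toolchains. Filtering always precedes resampling
so the low-pass doubles as the anti-alias filter; integer ratios decimate,
others fall back to polyphase resampling.

Baseline correction subtracts, per channel, the mean of the subject's
baseline recording from each task recording (the baseline itself becomes
zero-mean). Whether this correction belongs in the signal domain or the
feature domain is genuinely ambiguous in the workload literature; the signal
domain is the literal reading of "deducting the mean of the baseline data"
and is what the package does. Windows are non-overlapping one-second
segments, trailing remainder dropped, giving 600/600/300/300 windows per
condition.

Each task's window sequence is further split into three 200-window
*time-window partitions*. For the 600-window tasks these are [0, 200),
[200, 400), [400, 600); for the 300-window tasks, slice 1 is [0, 200) and
slices 2 and 3 are both [100, 300). Two published descriptions of the third
slice conflict ([200, 300) vs [100, 300)); the package adopts the [100, 300)
definition and makes the ranges configurable. All indices are 0-based and
half-open, so "windows 1–200" maps to [0, 200). Partition 3 is the default
throughout, and every analysis below operates on 200 windows per
subject-condition pair — balanced classes by construction.

## Biomarker feature sets

All spectral estimates use Welch's method with 125-sample (0.5 s) Hann-tapered
segments at 50% overlap: three averaged periodograms per 1-second window at
2 Hz resolution, the coarsest grid that still covers the 4 Hz lower band
edge. Band intervals are half-open [lo, hi) so the shared 7 and 13 Hz edges
are counted once.

* **Band powers** (9-dimensional): integrated Welch power, $\sum_k P(f_k)\,
  \Delta f$, for alpha, beta and theta at Fz, Cz and Pz.
* **Relative gamma** (3-dimensional), per channel:
  $\mathrm{RG} = \overline{P}(25\text{–}45\,\mathrm{Hz}) \,/\,
  \overline{P}(4\text{–}13\,\mathrm{Hz})$, where $\overline{P}$ is the *mean*
  PSD over the band's bins. A 4–23 Hz slow-band variant is exposed as an
  argument but the 4–13 Hz definition is canonical.
* **Brain load index** (1-dimensional):
  $\mathrm{BLI} = \theta(\mathrm{Fz}) / \alpha(\mathrm{Pz})$, integrated
  band powers.

Integrated power and mean PSD differ by a bandwidth factor; both conventions
appear only inside ratios or as features that are subsequently z-scored, so
the distinction is documented rather than consequential. Power is averaged
linearly (not in dB). Ratios are undefined for exactly-zero denominators;
such windows (impossible for generator output, possible for flat-zero input)
are dropped with a warning naming the offending window indices rather than
propagating NaN.

## The autoencoder

The latent representations come from a fully connected autoencoder written
from scratch in the package: encoder layers of widths 50-50-50 (the last is
the 50-unit code $Z = f(X)$), a mirrored decoder, and a linear output layer
reconstructing $X' = g(Z)$. The loss is the batch RMSE
$L = \sqrt{\tfrac1N \sum_i (x_i - x'_i)^2}$ with $N$ the number of scalar
entries, minimized by plain minibatch SGD. Defaults, all overridable:
learning rate 0.01, batch 32, at most 200 epochs, early stopping after 20
epochs without improvement, Glorot-uniform initialization from the run seed,
ReLU hidden activations with a linear output (the standard pairing for
real-valued reconstruction under an RMSE loss). Inputs are z-scored per
column using training-data statistics stored in the model — SGD on raw µV²
scales diverges — and the returned weights are those of the best epoch, so
the reported loss is the trace minimum. Backpropagation is verified against
central finite differences (`ae_gradient_check()`, smooth activations,
relative error below 1e-5).

Two design points deserve flagging. First, the published architecture names a
100-unit input layer, which cannot equal the 9-, 3- or 1-dimensional feature
sets; the package sets the input width to the data dimensionality and keeps
the 50-50-50 hidden stack. Second, feeding the 1-dimensional BLI into a
50-unit code is an *overcomplete* and frankly degenerate mapping; it is
implemented as specified and works mechanically, but users should expect the
latent BLI representation to add little beyond a nonlinear re-coordinatization.

## Classification protocol

Six deterministic classifiers form the default bench, each at the
configuration the protocol fixes: RBF-kernel SVM (cost 1, kernel width
$1/(d \cdot \overline{\mathrm{Var}})$ from training data), AdaBoost (SAMME
over depth-1 decision stumps, 50 rounds; a 10-round variant via
`n_estimators`), LDA, a one-vs-rest ridge classifier on a ±1 indicator matrix
($\lambda = 1$), random forest (100 trees), and KNN ($k = 5$, Minkowski
$p = 2$). A small feedforward softmax network is available under the name
`dbn` as an optional seventh entry — no architecture is published for the
deep-belief variant, so the adapter uses two 64-unit ReLU layers without
greedy pretraining and is excluded from default runs.

Evaluation is stratified 5-fold cross-validation over condition labels, with
accuracy, per-class precision and per-class F1 computed per fold and averaged.
Everything data-dependent is fold-safe by default: z-scoring statistics and
the autoencoder are fitted on the four training folds only, so latent
features never see their own test rows. A published table computed this both
ways could not be disambiguated; `ae_global = TRUE` reproduces the optimistic
variant in which one autoencoder sees all rows. Folds are drawn at the
window level, pooling windows across subjects, which matches the protocol's
window-count bookkeeping but inflates accuracy relative to a subject-held-out
split (adjacent windows of one subject are highly correlated and can land on
both sides of a fold boundary); `group_filter` supports nurse-only and
control-only re-analyses, and subject-grouped CV is an acknowledged, sharper
alternative left to the user's judgement.

## Diagnostics

`tsne_embed()` wraps exact (theta = 0) t-SNE at the protocol's settings:
perplexity 10, 5000 iterations, learning rate 1000. The protocol's phrase
"perplexity to 10%" is read as perplexity = 10 — a percentage is not a valid
perplexity — with `perplexity_frac = 0.10` available for the literal reading.
Rows are canonically sorted before the seeded initialization and unpermuted
afterwards, making the embedding invariant to input row order.
`feature_summary()` reports per-condition means and *population* (divide by
n) standard deviations.

## Problem sizes and numerical choices

The test suite and the acceptance script run on reduced cohorts chosen as the
package's own verification sizes: 5 nurses + 5 controls (8 000 windows after
partitioning) for the end-to-end signal-recovery and null checks, 3 + 3 for
the effect-size monotonicity sweep, and 2 + 2 for the full benchmark
enumeration. Autoencoder epoch budgets are similarly reduced (10–30 epochs)
where only the plumbing, not the asymptotic fit, is under test. Headline
accuracies from 75-participant human data are not reproducible from a
desk-scale synthetic cohort and are deliberately not asserted anywhere; the
tests establish properties — formula correctness to 1e-12, spectral
calibration within 10%, above-chance signal recovery by exact binomial test,
chance-level nulls, fold-safety — rather than point values.

Other fixed conventions: ties in classifier score vectors break toward the
first class; stratified folds deal shuffled within-class rows round-robin;
constant feature columns get unit scale during z-scoring to avoid division by
zero; EDF export quantizes to 16 bits over each channel's physical range, so
round-trips are exact to half a quantization step.

## Known limitations

Synthetic validation bounds what can be claimed: the pipeline demonstrably
recovers condition structure that the generator plants, at the effect size
the user chooses, and shows chance-level behaviour when no structure exists —
it does not certify any particular accuracy on human TSST recordings.
Window-level CV optimism, the absent artifact model, and the degenerate
1-to-50-dimensional BLI embedding are the three caveats most likely to
surprise users coming from the published numbers.

A related expectation to calibrate: on this generator the latent
representations classify *about as well as* the raw features, not better.
The autoencoder's advantage on real recordings is usually attributed to its
suppressing artifactual and non-stationary variance that the raw biomarkers
carry; synthetic windows are clean and stationary by construction, so there
is little for the code layer to remove and the raw-vs-latent contrast is
approximately a wash. Observing latent ≈ raw here is therefore the expected
behaviour of a correct implementation, not a deficiency.
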