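---
title: "Classifying EEG segments with a TanhReLU convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying EEG segments with a TanhReLU convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Major depressive disorder (MDD) screening from resting-state EEG is usually
framed as binary classification of short multichannel segments: each
4-second window (1024 samples at 256 Hz, 20 electrodes in the 10--20
montage, ECG included) is labelled MDD or healthy control.  `tanhrelunet`
implements a compact convolutional network for this task, built around a
hybrid activation that fuses the hyperbolic tangent with a half-slope linear
tail, together with everything needed to exercise the pipeline end to end
without access to clinical data: a seeded synthetic EEG generator, EDF
ingestion, the training recipe, and subject-wise leave-one-out validation.

## The TanhReLU activation

The activation is piecewise, governed by a segmentation parameter $a > 0$
(default $a = 0.25$):

$$\mathrm{TanhReLU}(x) = \begin{cases}
  \tanh(x) = \dfrac{e^x - e^{-x}}{e^x + e^{-x}}, & |x| \le a \\[4pt]
  0.5\,x, & |x| > a
\end{cases}$$

Its derivative is $1 - \tanh(x)^2$ on the inner branch and $0.5$ on the
tails.  For $a \lesssim 1.2$ the derivative therefore lies in $[0.5, 1]$
everywhere: gradients can neither vanish (the tails never saturate, unlike
tanh) nor die (the negative tail has slope $0.5$, unlike ReLU), which is the
activation's motivation.

Two properties deserve explicit care:

* **Discontinuity.** Taken literally, the definition jumps at $|x| = a$:
  $\tanh(a) \ne 0.5a$ for all $a \ne 0$, with gap $\tanh(a) - 0.5a$
  ($\approx 0.12$ at $a = 0.25$).  We implement the printed definition
  verbatim — the jump is real and measurable via `discontinuity_gap()` — and
  additionally expose a continuity-corrected variant
  (`continuity_correction = TRUE`, off by default) whose tail is shifted to
  $\tanh(a)\,\mathrm{sign}(x) + 0.5(x - a\,\mathrm{sign}(x))$.
* **Tie-break.** The boundary $|x| = a$ takes the tanh branch, for the
  forward value and the derivative alike, so tests are deterministic.

```{r, eval = FALSE}
library(tanhrelunet)
tanhrelu(c(0, 0.25, 1, -1))     # 0, tanh(0.25), 0.5, -0.5
range(tanhrelu_grad(seq(-10, 10, 0.01)))   # 0.5 .. 1
discontinuity_gap(0.25)         # ~0.1199
```

## Architecture

The network (defaults in `network_config()`) is deliberately small:

1. **Depthwise "high-filter" convolution** — 20 filters of $5 \times 5$,
   one per electrode, valid padding, stride 1: each channel's $32 \times 32$
   plane (the row-major reshape of its 1024-sample window) is filtered
   independently.  $20 \times 32 \times 32 \to 20 \times 28 \times 28$.
2. **Standard convolution** — 20 filters of $5 \times 5$ spanning all 20
   maps: $\to 20 \times 24 \times 24$.
3. **Flatten** to 11520 features, then an **hourglass fully connected
   block** with strictly decreasing widths $128 \to 32 \to 1$.
4. **Sigmoid head** giving the MDD probability; threshold 0.5, ties
   positive.

Batch normalization follows each convolution and each hidden fully
connected layer, before the activation (momentum 0.1, $\varepsilon =
10^{-5}$).  Weights are Glorot-uniform from a single seeded stream; biases
start at zero.

Design points the reference architecture leaves open, fixed here as package
conventions: no pooling, stride or padding anywhere (none is mentioned, and
two valid $5\times5$ convolutions already reduce $32^2$ to $24^2$); the
second convolution has width 20 symmetric with the first; the fully
connected widths $128/32$; row-major window reshaping; and the 0.5 decision
threshold.  All are exposed in `network_config()` rather than hard-coded.

## Training recipe

`train_config()` defaults: SGD with learning rate $0.01$ and weight decay
$10^{-6}$ (applied to weight tensors only — never biases or batch-norm
parameters), mean-squared-error loss on the sigmoid output, batch size 15,
at most 40 epochs, early stopping with patience 10 on the validation loss,
best-epoch parameters (and batch-norm running state) restored.  The segment
list is shuffled once with a stated seed and split 85/15 into training and
validation; batches keep their composition across epochs, which makes runs
bit-reproducible and makes a zero-learning-rate run provably flat.  A
trailing batch of size 1 is dropped (batch statistics need two examples).

`loo_validate()` wraps this in leave-one-out validation.  The default unit
is the **subject**: all windows of the held-out recording are scored by a
network that never saw any window of that subject, which is the clinically
honest protocol.  Segment-wise hold-out is also available (`unit =
"segment"`), since shuffling the complete pool of windows before splitting
— a protocol that inflates reported figures on this task —
leaks within-subject correlations into training.  Reports name the unit.
Per-fold seeds derive deterministically from the master seed and fold
index, so folds are independent yet the whole run reproduces exactly.

## Synthetic EEG generator

`synth_config()` states a small world in which the pipeline is verifiable:

* 20 channels at 256 Hz (the emulated montage geometry), default 40 s per
  subject and 6 subjects per class;
* per channel: an alpha-band sinusoid (10 Hz, random phase per channel)
  whose amplitude is `alpha_amp_control` (1.0) for controls plus
  `alpha_amp_effect` (1.0) for the MDD-like class — a fourfold alpha-power
  contrast at the defaults;
* unit-variance $1/f$-shaped background noise (white Gaussian noise shaped
  in the frequency domain with amplitude $1/\sqrt{f}$ above 1 Hz, the
  classic EEG spectral profile) at scale 1.0, plus white sensor noise at
  scale 0.2;
* a log-normal per-subject amplitude multiplier (sd 0.1) so subjects are
  exchangeable but not identical.

Everything is a pure function of `(seed, subject_index, label)`.  The
noise scales were chosen once so that the class contrast is clearly
learnable from single windows yet far from trivial (in-band noise dilutes
the nominal 4:1 power ratio to roughly 3.4:1).  What the generator does
*not* emulate: eye-blink and movement artifacts, inter-channel covariance
from volume conduction, non-stationarity, and any true MDD signature — the
real clinical contrast is unknown and not claimed.  A green end-to-end test
therefore establishes that the pipeline can learn a genuine subject-level
spectral contrast without label leakage; it says nothing about clinical
performance.

With `alpha_amp_effect = 0` the two classes are exchangeable by
construction, which gives the null calibration: subject-wise leave-one-out
accuracy should hover near chance, and a permutation test on per-subject
alpha power should be non-significant in the vast majority of seeded
replicates.

## Numerical choices

* Convolution is cross-correlation (no kernel flip), as in every deep
  learning framework.
* All backward passes are exact analytic gradients, verified against
  central finite differences (relative error $10^{-4}$, $h = 10^{-5}$) in
  the test suite; TanhReLU checks avoid a $10^{-3}$ neighbourhood of the
  branch points where the function is non-differentiable.
* Batch normalization uses the biased variance for normalization and the
  unbiased variance for the running estimate; training statistics require a
  batch of at least 2.
* The heavy kernels (both convolutions, channel-wise batch normalization,
  the fused SGD update) are implemented in C++ with BLAS for the matrix
  contractions; everything is double precision and single-threaded, so
  results are bit-reproducible for a fixed seed.
* Metrics with undefined denominators (e.g. sensitivity with no positives)
  return `NaN` rather than erroring.
* EDF I/O uses the standard 16-bit encoding; the writer sets each channel's
  physical range symmetrically to its absolute maximum, bounding the
  round-trip error by $\max|x| / 2^{15}$ per channel.

## Limitations

**Subject-wise generalization on the synthetic world.**  The generator
draws each channel's oscillation phase once per recording, and at the
default 10 Hz a 4-second window spans exactly 40 cycles — so every window
of a subject repeats the same phase pattern.  These patterns are linearly
separable subject fingerprints, and they sit exactly where the
architecture is strongest: the depthwise layer can realize one matched
filter per channel.  Stochastic gradient descent therefore reaches perfect
training and validation accuracy by recognizing *subjects* rather than the
amplitude contrast, and because the validation split is drawn from the same
subjects as the training split, early stopping cannot see the problem.  The
consequence, which the test suite measures rather than hides: segment-wise
hold-out accuracy is essentially perfect, while subject-wise leave-one-out
accuracy on the default synthetic world collapses to near chance even
though the class contrast is trivially separable at the subject level by
alpha-band power.  This is a genuine property of this architecture and
training protocol on this world, and it is the reason subject-wise
validation is the package default: a protocol that cannot be fooled by
within-subject leakage is precisely the one that reveals when a model has
learned identity instead of pathology.  Randomizing the oscillation phase
per window (breaking the fingerprint) or validating across subjects inside
each fold would change the outcome, but both would depart from the stated
training protocol and generator, so neither is the default.

The package trains on CPU in pure double precision and is sized for the
small cohorts of its domain, not for large-scale imaging.  The EDF codec
covers the common continuous-recording layout (EDF and EDF+C signals,
16-bit samples) and resamples mixed-rate channels by linear interpolation;
exotic EDF+ annotation streams are ignored.  Reproducing clinical-grade accuracies requires a real clinical dataset and is
expressly out of scope: the integration path (`read_edf()`, manifests, the
command-line `train`/`evaluate`/`loo` tools) accepts such data, but all
self-contained evidence comes from the synthetic world described above.
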