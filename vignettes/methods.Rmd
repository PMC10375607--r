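---
title: "Methods: sample-wise 12-lead ECG delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-wise 12-lead ECG delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgdelin)
```

## The model

Delineation is cast as per-sample classification. Each 512-sample beat
window $x \in \mathbb{R}^{512}$ is mapped to a probability sequence
$p \in [0,1]^{512 \times 4}$ over the classes isoelectric, P, QRS and T.
The network is a stack of $L$ 1-D convolutions (kernel 3, stride 1,
same padding, ReLU) with filter counts $8 \cdot 2^{k}$,
$k = 0, \dots, L-1$, followed by a recurrent head whose hidden state is
read out at *every* timestep and projected through a shared dense layer
with a softmax. Thirteen family members are enumerated: $L = 1\ldots4$
with an LSTM head and $L = 1\ldots9$ with a BiLSTM head; GRU and BiGRU
heads exist for comparison.

Two structural choices keep the task well-posed:

* **No pooling, same padding.** Any temporal downsampling would destroy
  the per-sample output the task needs; the conv stack preserves length
  512 exactly, which is property-tested for all 13 configurations.
* **Per-timestep readout.** The recurrent head consumes the feature
  sequence directly and emits one output per timestep; a bidirectional
  head therefore sees both the past and the future of each sample, which
  is what distinguishes, say, a T offset from a P onset on the baseline.

Training minimizes categorical cross-entropy with Adam. Loss and all
metrics are computed **only over non-padded samples** (positions
`< valid_length`). Including the zero-padded tail, which is always
"isoelectric", would inflate every metric with free wins; a padding
mask makes the numbers interpretable. The reference recipe is 300
epochs, batch 8, learning rate $10^{-5}$; the desk-scale experiments in
the tests use 20 epochs at $10^{-3}$ with the same machinery.

Numerical choices: Glorot-uniform initialization; LSTM forget-gate bias
initialized at 1 so the memory cell starts open and long-range influence
is representable from the first forward pass; global gradient-norm
clipping at 1.0 (the standard guard against exploding recurrent
gradients — without it, occasional late-training loss spikes occur at
desk-scale learning rates); softmax rows are max-stabilized; argmax ties
resolve deterministically to the lower class index. Gradients of every
head are verified against central finite differences in the test suite.

## Wavelet denoising

Signals are denoised by multilevel DWT with symmetric (half-point)
boundary extension, soft thresholding of all detail bands at the
universal threshold $\hat\sigma\sqrt{2\ln n}$,
$\hat\sigma = \mathrm{median}(|d_1|)/0.6745$ (VisuShrink), and exact
reconstruction. The approximation band is untouched. Defaults: bior6.8,
level 8. At 500 Hz an 8-level decomposition puts everything below
$\approx 1$ Hz — baseline wander — into the approximation band, so the
threshold never touches the ST segment's low-frequency content. The
filter banks (Daubechies, symlet, biorthogonal-spline families) are
standard published constants; single-level analysis/synthesis and
multilevel perfect reconstruction are property-tested to $10^{-8}$.

SNR is $10\log_{10}(\sum r^2/\sum(r-e)^2)$ dB. Which signal is the
reference is a genuinely open choice, so both modes are exposed:

* `reference = "clean"` — synthetic data, where the noise-free source is
  known. This is the mode with an unambiguous interpretation.
* `reference = "retained"` — real recordings, where no clean signal
  exists: the raw input is the reference and the denoised output the
  estimate, so the score measures retained signal relative to the
  removed component. It makes corpus-level SNR a checkable pipeline
  statistic rather than an unverifiable claim.

Exact equality of reference and estimate reports `Inf` (a distinct
"infinite SNR" outcome, not an error); a zero reference is a parameter
error.

## Segmentation and splits

A beat spans one P onset to the next. Spans missing a complete QRS
triplet are excluded (and tallied); the trailing partial beat is always
dropped. Windows shorter than 512 samples are zero-padded, longer ones
clipped at 512 — clipping is logged, and at physiologic heart rates with
10-s records it is rare (a 512-sample window covers rates down to
$\approx 59$ bpm; slower beats lose only their terminal baseline).
Labels use closed intervals $[\mathrm{onset}, \mathrm{offset}]$ on
0-based sample indices. Where annotation intervals overlap, precedence
is QRS > T > P: QRS boundaries are the most reliably annotated, and
T/P overlap is the documented hard case.

Beat-based splitting shuffles within each lead with a fixed seed and
partitions 80/12/8 by the floor rule; patient-based splitting assigns
whole records by id range (default 1–180/181–190/191–200) with no
randomness, so no subject contributes beats to two sets. Conservation
and disjointness are asserted as properties.

One model is trained on beats pooled from all 12 leads and evaluated per
lead (a per-lead breakdown of a single model is the only arrangement
consistent with reporting one row per model *and* per-lead curves for
the best one). Macro averages are unweighted over the four classes;
ratios with zero denominators are reported as missing and excluded from
macros rather than silently zeroed.

## The synthetic generator

Each beat is a sum of five Gaussian bumps
$a\,e^{-(t-\mu)^2/2\sigma^2}$ (P, Q, R, S, T) with physiologic defaults
(R: 1 mV, σ = 12 ms; T: 0.3 mV, σ = 50 ms; P: 0.15 mV, σ = 20 ms).
Ground-truth boundaries use the ±3σ convention (>99% of each bump's
mass), QRS spanning $[\mu_Q - 3\sigma_Q,\ \mu_S + 3\sigma_S]$;
configurations whose truth intervals would overlap are rejected at
construction, so fixtures are valid by force. Beats are tiled at RR
intervals with ±5% uniform jitter (70 bpm default), projected onto the
12 leads by fixed scalings of one source — a crude single-dipole
surrogate with aVR inverted, adequate because the pipeline treats leads
independently — and only then corrupted with white noise (0.05 mV
default) and 0.3 Hz sinusoidal baseline wander, so labels remain exact
at any noise level. Corpora are written as genuine WFDB signal files
plus per-lead MIT-format annotation files and re-read through the same
parsers real data uses.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: pathological morphologies (AF, bundle
branch block, ST deviation), biphasic or inverted T waves outside aVR,
inter-subject morphology variation beyond amplitude scaling, muscle
artifact, electrode motion, or annotation disagreement between human
annotators. Synthetic results validate the machinery, not clinical
performance.

## Desk-scale experiment sizes

The test suite and acceptance script run, by design, at desk scale: a
3-record corpus for I/O and counting checks, an 8-record corpus for the
pipeline, and the reduced recovery experiment — 2 conv layers, BiLSTM
with 16 units per direction, 200 noise-free training beats, 20 epochs at
learning rate $10^{-3}$ — which the acceptance property requires to
exceed 90% masked sample accuracy on held-out beats. Full-scale
reproduction (200 records, model 11, 300 epochs at $10^{-5}$) uses the
identical code path via `run_pipeline()` with a WFDB input directory and
`config_id: 11`, and is a multi-hour computation.

## Delineation post-processing

Predicted label streams are smoothed by relabeling non-zero runs shorter
than `min_run` (default 10 samples = 20 ms at 500 Hz) to isoelectric —
long enough to kill single-sample flicker, an order of magnitude shorter
than any plausible wave — then maximal runs become intervals. Matching
against truth is greedy one-to-one by overlap with both boundary
discrepancies required within 150 ms (75 samples), the conventional
acceptance window in the delineation literature; matched pairs yield
onset/offset errors in samples and ms. With `min_run = 1` extraction
exactly inverts label-stream construction, which is the round-trip
property the tests rely on.

## Known limitations

* The DWT supports a fixed set of ten wavelets; adding one means adding
  its filter bank.
* The recurrent cores process one sequence at a time; training is
  single-threaded and sized for hundreds-to-thousands of beats, not
  millions.
* The WFDB reader covers format 16 single-segment records — the layout
  the target database uses — not the full format zoo.
* Patient-based splitting requires integer-valued record ids, as in the
  target database's `1 … 200` naming.
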