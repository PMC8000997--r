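---
title: "Detecting premature ventricular contractions with metric-learned embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting premature ventricular contractions with metric-learned embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvcmetric)
```

## The problem and the model

A premature ventricular contraction (PVC) is an ectopic beat initiated in
the ventricles. On a single-lead ECG it is recognisable by a broad,
abnormally shaped QRS complex, a missing P wave, early arrival relative to
the sinus rhythm, and a full compensatory pause — the RR interval before
plus after the PVC equals two base RR intervals. The task is binary
classification of individual heartbeats (normal vs. PVC) in long
ambulatory recordings sampled at 360 Hz on the modified limb lead II.

Rather than hand-designing morphology features, the package learns a
distance structure. A 1-D convolutional network `f(x; θ)` maps each
433-sample R-centred beat to an F-dimensional embedding; training pulls
same-class embeddings together and pushes cross-class embeddings apart in
cosine geometry; and a K-nearest-neighbour vote over the training
embeddings classifies new beats. The three stages are deliberately
decoupled — segmentation, embedding, classification — and every stage is
exposed as ordinary R functions.

### Beat extraction

Each annotated R peak becomes a window of 433 samples with the R sample
exactly at offset 216 (0-based), i.e. `(window - 1) / 2` samples on each
side, inclusive. Windows that would overrun a record edge are dropped, not
padded: padding would invent signal at precisely the window positions the
convolutional layers weight most symmetrically. Each extracted beat is
amplitude-normalised elementwise with `tanh(x)`, which is monotone, odd,
nearly linear around zero, and saturates large R-peak deflections into
(-1, 1). The normalisation acts on raw millivolt values per beat; no
rescaling precedes it.

Annotation symbols map to classes as: `V` is the PVC (positive) class;
the normal class is the AAMI N group `{N, L, R, e, j}` — normal,
left/right bundle branch block, atrial and junctional escape. The
grouping matters: the training split contains records whose beats are
exclusively bundle-branch block, and published beat totals for this split
are reachable only when those count as normal. Every other symbol
(other arrhythmias, paced beats, non-beat annotations such as rhythm
change markers) is discarded. The mapping is a configuration knob of
`extract_beats()`.

### Record partition

`partition_records()` implements the standard inter-patient split of the
48-record ambulatory database: 22 training records, 22 test records, and
four paced-rhythm records (102, 104, 107, 217) excluded following the
AAMI recommendation. Cross-validation at the beat level would leak
labels, because one subject's beats are highly self-similar; the split
keeps each subject entirely on one side.

## The embedder

The default architecture stacks eight convolutional groups. Each group is

```
conv(k) -> batch norm -> PReLU -> conv(k) -> batch norm -> PReLU -> pool(2)
```

with 'same' zero padding on the convolutions, so only the pool changes
the temporal length: 433 → 216 → 108 → 54 → 27 → 13 → 6 → 3 → 1 (odd
lengths floor; the trailing sample is dropped). After the eighth pool a
single time step remains and the embedding is simply the channel vector
there, so F equals the last group's kernel count. Defaults: channels
`32, 32, 64, 64, 128, 128, 32, 32` with kernel sizes
`33, 17, 17, 9, 9, 5, 5, 3`; only the first group's `32@33` is fixed by
the reference design, the rest are package defaults and fully
configurable. `F ∈ {2, 8, 32, 64}` reproduces the feature-count sweep;
32 is the default. For configurations with fewer groups the final length
exceeds one and the channel activations are averaged over time — at
length 1 the two conventions coincide.

Max pooling is the default: the R wave is a sharp, high-amplitude
landmark, and keeping the strongest local response preserves it; average
pooling is available for the pooling ablation. Min pooling is not
offered — under PReLU activations it collapses activity toward zero.

The network layers use cross-correlation, as deep-learning frameworks
do. The standalone `conv1d_forward()` implements the flipped-kernel
textbook convolution `y_j = Σ_i x_i h_{j−i}`; for learned kernels the two
are equivalent up to a kernel flip, and the test suite checks the layer
composition against oracles built from the standalone operator with
reversed kernels.

Batch normalisation uses the population (1/m) batch variance in train
mode, exponential running statistics (momentum 0.1) in eval mode, and
eps = 1e-5. PReLU slopes are per-channel learnable parameters initialised
at 0.25. Weights draw from the uniform fan-in distribution
`U(−1/√fan_in, +1/√fan_in)` under a fixed seed. All arithmetic is double
precision.

## Mining and loss

For a mini-batch, embeddings are L2-normalised and the full cosine
similarity matrix `S` is formed. The multi-similarity miner selects, for
each anchor `i`:

- negative pairs `j` (different class) with
  `S_ij > min_{y_k = y_i, k ≠ i} S_ik − ε`;
- positive pairs `j` (same class, `j ≠ i`) with
  `S_ij < max_{y_k ≠ y_i} S_ik + ε`.

In words: keep only negatives at least as similar as the anchor's
worst positive (minus slack), and positives no more similar than the
anchor's best negative (plus slack). Every (anchor, positive, negative)
combination of the selected pairs forms a triplet with loss

```
L(a, p, n) = max{ (S_an − S_ap) + margin, 0 }
```

and the batch loss is the mean over triplets with non-zero loss (zero if
none). Gradients flow through the similarity matrix and the row
normalisation back into the network; optimisation is Adam at learning
rate 1e-4 with zero weight decay, batch size 32.

Two conventions deserve a note. First, the loss is written for
*similarities*: a literal distance-form loss applied to a similarity
would reward dissimilar positives, so the sign convention above is used
throughout, and it is zero exactly when the positive beats the negative
by the margin. Second, similarities are always the *normalised* cosine —
in mining, in the loss, and in the KNN — matching the named distance of
the reference configuration; a raw dot-product reading of the same
equations would make the loss scale-dependent.

Strict inequalities in the miner mean that at an exact tie (e.g. fully
collapsed embeddings with ε = 0) nothing is selected; any positive slack
restores the intuitive behaviour (everything mined, every triplet at
exactly the margin loss). Anchors lacking a same-class or cross-class
partner contribute no triplets; a single-class batch mines nothing and
single-class *training data* is an error.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `margin` | 0.1 | required cosine gap; larger = harder objective, less stable training |
| `epsilon` | 0 | miner slack; larger admits more (easier) triplets |
| `batch_size` | 32 | similarity matrix is computed per batch |
| `learning_rate` | 1e-4 | Adam step size |
| `epochs` / `patience` | 40 / 5 | early stopping on training-loss plateau |
| `K` | 1 | KNN votes; even splits fall back to the nearest neighbour |
| `window` | 433 samples | beat length at 360 Hz |

The margin/epsilon defaults are the selected operating point of the
reference study (margin 0.1, ε 0); the sweep harness `run_sweep()`
re-evaluates the margin grid {0.1, 0.2, 0.4, 0.8} × ε and the K grid
{1, 3, 5, 9, 11}, the latter re-using a single trained embedder since K
only affects the vote.

## Denoising operators

The default pipeline applies **no** denoising — the convolutional
embedder tolerates the raw signal, and filtering alters beat morphology,
which is the classification signal itself. For the ablation:

- `notch_filter()`: linear-phase windowed-sinc (Hamming) band-stop FIR
  cascade at 60 Hz (power line) and 100 Hz (fluorescent lighting),
  designed at the record's actual sampling rate. Order 440 with ±8 Hz
  stop bands meets ≥ 20 dB attenuation at the notch and ≤ 1 dB ripple
  below 40 Hz at 360 Hz sampling; group delay is compensated and edges
  are reflection-padded.
- `median_baseline_remove()`: baseline = running median (71 samples)
  followed by running median (215 samples), subtracted from the signal;
  reflection padding at the edges. The short window strips beat
  features, the long one follows only the slow wander.

When both are enabled the FIR cascade runs first, then the median
baseline removal, matching the order in which the operators are listed
in the reference configuration.

## The synthetic generator

`generate_record()` emulates exactly the features the classifier relies
on, with one Gaussian bump per wave (P, Q, R, S, T) placed relative to
the R peak:

- **normal beat**: P bump 0.15 mV at −0.22 s, R 1.0 mV, narrow QRS
  (0.08 s), upright T;
- **PVC**: no P bump, wider (0.16 s) and taller (1.4 mV) QRS, T wave of
  opposite polarity to R. The QRS polarity of real PVCs varies by origin
  and lead; the default is positive and configurable.

Rhythm patterns follow the clinical definitions (bigeminy: every other
beat; trigeminy: every third; quadrigeminy: every fourth; couplet: two
consecutive PVCs; `random`: i.i.d. with probability `pvc_fraction`).
Each PVC is scheduled early by `prematurity × base_rr` (default 0.25 ×
0.8 s) while the following sinus beat stays on the grid, so every
isolated PVC satisfies the full-compensatory-pause identity to within
one sample. Noise defaults are modest but non-zero — 0.02 mV Gaussian,
0.01 mV at 60 Hz and 100 Hz, 0.05 mV baseline wander at 0.3 Hz — chosen
as plausible magnitudes for a reasonably clean ambulatory recording;
they are deliberately fixed and not tuned per experiment.

One integer seed drives all randomness of a record (rhythm draws, noise,
phases), and the pipeline's master seed fans out deterministically to
the record, weight-init and shuffling stages, so runs are reproducible
bit for bit.

What the generator does **not** emulate: beat-to-beat morphology
variability within a subject, heart-rate drift, motion artifacts,
electrode pop, atrial arrhythmias, multiform PVCs, or fusion beats. The
synthetic classes are separable by construction (QRS width/amplitude, P
absence, T polarity), so passing the end-to-end tests demonstrates that
the machinery — segmentation, mining, loss, gradients, KNN — works and
converges; it does not certify clinical-grade accuracy on real
recordings, which contain genuinely ambiguous beats.

## Numerical choices and degenerate inputs

- Pooling uses floor(L/2) and drops a trailing odd sample, which is what
  makes the 433 → 1 trajectory exact.
- Batch norm refuses train mode on a single value; eval mode always uses
  running statistics.
- `beat_metrics()` reports a metric with zero denominator as `NA`, never
  silently 0, and refuses an all-zero confusion matrix.
- KNN vote ties (even K) resolve to the nearest neighbour's label,
  consistent with the K = 1 limit.
- The miner's min over same-class similarities excludes the self-pair.
- Windows are 0-based inclusive, as in the annotation format.
- Mean batch loss averages only triplets with non-zero loss; satisfied
  triplets neither dilute the loss nor contribute gradient.

## Problem sizes used in the checks

The automated checks train a reduced-channel eight-group embedder
(channels 4-4-8-8-8-8-8-8, kernels 17-9-9-5-5-3-3-3, F = 8) on 4,000
synthetic beats and evaluate on 2,000 held-out beats from an
independently seeded record, a size at which training converges in a few
epochs and a couple of minutes on one CPU core while exercising every
stage at full window length. Unit tests use smaller records (tens of
beats) and a tinier variant of the same architecture. The full-scale
default architecture (F = 32) is exercised for shape and determinism,
not trained in the test suite; training it on the full database is an
hours-long job driven by the same `run_pipeline()` call with a
`wfdb`-sourced configuration.

## Known limitations

- The embedder is implemented in vectorised R; it is fast enough for the
  synthetic studies and for embedding full records, but full-database
  training is orders of magnitude slower than a GPU framework.
- Binary task only (normal vs. PVC); the label map can group other
  symbols but the pipeline does not do multi-class.
- Single lead; no multi-lead fusion.
- R-peak positions are consumed from annotations; no detector is
  included.
- The WFDB reader/writer covers the single-signal format-16 subset this
  package writes, not the full format family.
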