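---
title: "Semi-supervised speech deception detection with fused acoustic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised speech deception detection with fused acoustic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Deception leaves measurable traces in speech: deceptive utterances tend to
show an elevated fundamental frequency, altered energy dynamics, and changed
pausing behaviour. Labeled deception corpora, however, are small and
expensive to build, which makes purely supervised classifiers brittle.
`deceptr` implements a semi-supervised detector that learns from a small
labeled subset $D_L = \{X_L, Y_L\}$ together with a large unlabeled pool
$D_U = \{X_U\}$.

Each utterance is represented twice:

* **3D mel-spectrum** $X_{CNN}$: a 64-band log-mel spectrogram (25 ms
  Hamming window, 10 ms hop, `log(energy + 1e-10)` compression) stacked with
  its first- and second-order regression deltas and resized bilinearly to a
  square three-channel image. This view feeds a student/teacher
  convolutional network.
* **IS09 acoustic statistics** $X_{AE}$: the Interspeech-2009 emotion
  challenge vector — 16 low-level descriptors (zero-crossing rate, RMS
  energy, autocorrelation pitch normalized to 500 Hz, harmonics-to-noise
  ratio, HTK-style MFCC 1–12) and their deltas, each collapsed by 12
  functionals (mean, stddev, kurtosis, skewness, max, min, relative extremum
  positions, range, regression offset/slope/MSE), $16 \times 2 \times 12 =
  384$ dimensions. This view feeds a bottleneck autoencoder.

The **student CNN** is two blocks of three padded 3×3 convolutions
(BN + ReLU) with 2×2 max-pooling between blocks, an unpadded 3×3
convolution, two padded ones, and global average pooling to an embedding
(channel widths 32/64/(128, 64, 32) on 256×256 inputs). The **teacher** is a
structurally identical copy whose parameters are an exponential moving
average of the student's,
$\theta'' = \alpha_{ema}\,\theta' + (1 - \alpha_{ema})\,\theta$
(default $\alpha_{ema} = 0.99$), applied after every optimisation step. The
**autoencoder** compresses the 384-dim vector through 256–128–64–32
(BN + ELU) and decodes through 128–180–256–384; the 32-dim bottleneck is the
acoustic-statistics embedding. The bottleneck and the CNN embedding are
concatenated and classified by a dropout + linear + softmax head.

Training minimises

$$L = L_{ce} + \omega(t)\, L_{consis} + a\, L_{recon}$$

* $L_{ce}$: binary cross-entropy between the fused student prediction and
  the labels, on the labeled batch part;
* $L_{consis}$: the mean squared Euclidean distance between the student's
  fused embedding of a *perturbed* unlabeled input and the teacher's fused
  embedding of the same input — consistency regularization;
* $L_{recon}$: mean elementwise binary cross-entropy between the
  autoencoder reconstruction and the min–max-normalized input.

Three perturbations realise the semi-supervised wiring: $\eta$ (random
time-axis flip + random crop after edge-replication padding) is applied to
every spectrogram; $\eta'$ adds Gaussian noise to unlabeled spectrograms
entering the student; $\eta''$ adds Gaussian noise to unlabeled IS09 vectors
entering the autoencoder. The teacher sees only $\eta$-augmented views.
Optimisation is SGD with momentum 0.9 at learning rate 3e-4 under cosine
annealing, with dropout (prescribed value 0.8, realised as the keep
probability — see the design decisions below) in the autoencoder and fusion
head.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lr` | 3e-4 | initial SGD learning rate, cosine-annealed to 0 |
| `momentum` | 0.9 | SGD momentum (a design choice; only "small-batch SGD" is prescribed) |
| `dropout` | 0.2 | drop probability in AE and fusion head (the prescribed 0.8 read as a keep probability) |
| `alpha_ema` | 0.99 | teacher EMA smoothing |
| `omega_max` | 1.0 | consistency-weight ceiling, reached after a sigmoid ramp over the first 40% of epochs |
| `a` | 0.5 | reconstruction-loss weight |
| `noise_amplitude` | 0.3 | $\eta'$/$\eta''$ noise SD in robust-scale units (IQR/1.349 of the tensor) |
| `labeled_batch_fraction` | 0.25 | one labeled item per three unlabeled per batch |

The noise amplitude is anchored to each tensor's interquartile range so that
the single value 0.3 is meaningful for both standardized spectrograms and
min–max-normalized feature vectors.

## Design decisions where the design was open

* **Teacher scope.** The AE–Tea branch shares the autoencoder with the
  student and applies EMA to the CNN only; the teacher-side AE forward runs
  in evaluation mode (running BN statistics, no dropout) so the consistency
  target is stable. `ema_update()` itself is generic over any congruent
  parameter structure.
* **Consistency space.** The penalty is computed on fused *embeddings* by
  default (a `consistency_on = "probs"` mode penalises class-probability
  disagreement instead); the distance is the batch mean of squared norms,
  not additionally divided by the embedding dimension.
* **Reconstruction target.** For unlabeled items the autoencoder input is
  the $\eta''$-noised vector while the reconstruction target is the clean
  min–max-normalized vector — a denoising autoencoder, matching the noise
  enhancement's purpose. The decoder's terminal layer is linear + sigmoid
  (instead of BN + ELU as elsewhere) so reconstructions live in $(0,1)$,
  the domain of the BCE loss; the output-layer dropout site is moved one
  layer in, since dropout on the reconstruction itself would corrupt the
  loss target.
* **Dropout semantics.** Whether the prescribed dropout of 0.8 is a drop
  or a keep probability is ambiguous (both conventions are common). The
  drop-probability reading zeroes 80% of a 32-unit bottleneck, and on the
  desk-scale benchmark it reliably caps the model below the linear-probe
  reference (0.75 vs 0.92 on a representative corpus draw), while the
  keep-probability reading (drop 0.2) matches the reference; the default is
  therefore drop 0.2, with the drop probability exposed as a knob.
* **Classifier head vs the 8-unit row.** The architecture table's terminal
  "full connection 8" is kept as an auxiliary 8-dim projection on each
  branch; the binary classifier proper operates on the 32 + 32 fused
  concatenation with 2 softmax outputs. Both heads exist so either reading
  is testable.
* **Conv bias under BN.** Convolutions keep their bias parameters for
  structural fidelity, but a per-channel constant shift is removed by the
  following batch normalisation, so these biases have exactly zero gradient
  (a property the test suite asserts).
* **Flip + crop parameters.** The flip probability is 0.5 and the crop pad
  8 pixels; the scalar 0.3 that the training recipe assigns to unlabeled
  enhancement is read as the *noise* amplitude of $\eta'$/$\eta''$, since a
  flip/crop has no natural scalar intensity.
* **MFCC details.** HTK conventions: pre-emphasis 0.97, 26 triangular
  filters on the HTK mel scale over 0–8 kHz, DCT-II with
  $\sqrt{2/N}$ scaling, cepstral liftering 22. The pitch tracker searches
  50–500 Hz on the frame autocorrelation with a voicing threshold of 0.3
  (peak-to-lag-0 ratio); HNR is clamped to ±60 dB so silence and pure tones
  stay finite.
* **Split rounding.** The 9:1 train/test split takes
  `floor(0.9 N)` training items — 1,103 utterances give exactly 992/111 —
  stratified by class through a seeded permutation. The labeled subset is a
  stratified random sample of the training split.

## The synthetic corpus: what it emulates and what it does not

No public corpus accompanies the method, so the package ships a generator
(`generate_corpus()`) that emulates the *statistical shape* of a
werewolf-game deception corpus: ~1,103 utterances of 2–8 s at 48 kHz
(configurable), a 521/1103 deceptive fraction, a 9:1 split, and a labeled
subset of configurable size. Each utterance is a voiced-speech proxy — a
jittered sawtooth source with a drifting F0 contour, three formant-like
resonators with per-utterance speaker variation, slow log-normal energy
modulation, pause gating, and additive noise. The deceptive class draws its
F0 mean (+10 Hz per separation unit against a 6 Hz speaker SD), energy
modulation SD (+0.08) and pause fraction (+1.5 points) from shifted
distributions, following the observation that lies tend to carry a higher
fundamental frequency.

The signals are *not* intelligible speech: there is no lexical content,
no real formant dynamics, no channel variability, no speaker identity
structure, and the class effect is planted rather than behavioural.
Passing tests therefore demonstrate that the pipeline — feature extraction,
the hybrid network, the semi-supervised losses and the trainer — correctly
recovers a class difference of the kind the method assumes, at an effect
size chosen to be clearly learnable. They do not certify recognition
accuracy on real deception data, and the headline accuracies reported for
the original corpus are not reproduced here because that corpus is not
available.

## Numerical choices

* Log-mel floor `1e-10`; FFT size is the next power of two above the window
  (2048 at 48 kHz / 25 ms).
* Regression deltas use the ±2-frame HTK window with edge replication.
* Bilinear resizing on the pixel-centre grid is the configuration-pinned
  interpolation.
* BN uses $\epsilon = 10^{-5}$ and running-statistics momentum 0.9;
  evaluation always uses running statistics.
* The sigmoid output is clamped to $[10^{-12}, 1 - 10^{-12}]$ so the BCE
  loss and its gradient stay finite.
* Weight init: He-uniform for convolutions, Xavier-uniform for dense
  layers, seeded.
* Degenerate inputs (silent frames, constant series) produce defined
  sentinels (F0 = 0, HNR = −60 dB, zero functionals) rather than errors.
* All randomness — synthesis, splits, init, batching, augmentation,
  dropout — flows through R's RNG, so a seed fixes the entire run;
  two runs with equal seeds produce identical loss traces.

## Problem sizes used by the tests and the acceptance script

The package's own benchmark (the "desk scale") uses 64×64×3 spectrogram
inputs with channel widths 8/16/(32, 16, 8) — the identical topology at
reduced width — on a 120-utterance corpus with class separation 2.5, 36
labeled training items (30%), batches of 8 (2 labeled + 6 unlabeled) and 15
epochs. At these sizes the full model trains in about 1.5 minutes, and a
ridge-logistic linear probe on the IS09 table provides the supervised
reference that the semi-supervised model is held against. Generator
property checks use shorter utterances (0.5–2 s) and 100–200 draws per
condition. The full 256-scale network is configuration-identical and is
validated through its shape trace and forward contracts.

## Known limitations

* The 256-scale network trains only slowly on a single CPU; the desk scale
  is the supported benchmark configuration.
* The consistency loss on raw fused embeddings is scale-dependent (its
  magnitude tracks the embedding scale); the probability-space mode avoids
  this at the cost of a weaker signal.
* The generator's class effect is stationary within an utterance; real
  deception cues are time-local and interact with content.
* Batches always contain at least one labeled item, so the supervised loss
  is defined at every step; a corpus with zero labeled training items is
  rejected.
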