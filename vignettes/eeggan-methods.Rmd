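---
title: "Adversarial augmentation of EEG frames: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial augmentation of EEG frames: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep models for brain–computer interfaces are starved for data: EEG
acquisition is slow, noisy and demanding for the subject. One remedy is to
train a generative adversarial network on the available recordings and add
its synthetic frames to the training set of a downstream model. `eeggan`
implements this workflow for single-channel EEG cut into 2-second,
500-sample frames (250 Hz): a recurrent generator and a convolutional
critic trained with the gradient-penalty Wasserstein objective, similarity
metrics to judge the generated frames, and a compressed-sensing
reconstruction benchmark that measures whether augmentation actually helps
a downstream task.

## Preprocessing contract

Raw traces are cleaned by replacing missing samples with the minimum
non-missing value, cut into contiguous non-overlapping frames (a trailing
remainder is dropped), pooled-normalized to zero mean and unit variance
with one global mean and one global *population* standard deviation
(stored for the inverse transform), and split 70/30 with a seeded shuffle.
Three choices deserve a note:

* **Pooled, not per-frame, normalization.** A single mean/sd pair over the
  whole corpus keeps relative amplitudes between frames intact, which is
  what both the critic and the reconstruction benchmark should see.
* **Population sd** (divide by *n*) rather than sample sd: fixed so the
  normalization examples in the tests are exact.
* **Split construction.** One permutation is drawn per seed and the
  *majority* block is read from its head. This makes `train_fraction`
  values `f` and `1 - f` with the same seed produce the same partition
  with the roles of train and test exchanged, and the train count is
  `round(f * n)` (half-up).

## Synthetic study corpus

Real motor-imagery benchmark recordings cannot be shipped, so the
generator of surrogate frames (`synthetic_config()`, `generate_frames()`)
emulates what matters for this pipeline: band-limited oscillations at the
canonical delta/theta/alpha/beta rhythms (one random-phase sinusoid per
band and frame, frequency uniform in the band, amplitude proportional to
the square root of the band's relative power), 1/f broadband noise
synthesized in the frequency domain with random phases (slope `alpha = 1`
by default, relative power 0.5), and a lognormal per-frame amplitude
jitter (10% by default). Default relative band powers (1, 0.7, 0.9, 0.4)
give the low-frequency-dominant spectrum typical of resting EEG. The
surrogate does **not** emulate motor-imagery class structure, event
markers, artifacts, or inter-channel covariance — so green tests say the
*method* behaves as specified on EEG-like signals, not that the trained
generator reproduces any particular clinical phenomenon.

Smoke-scale experiments in the tests use a single alpha band (8–13 Hz)
plus 20% noise: a sharply structured, easily-learned target that makes
convergence checks meaningful at desk scale.

## The adversarial pair

**Generator.** A 1000-dimensional noise vector (U[0, 1] by default;
Gaussian available — the architecture description mentions both and the
more specific statement wins) is read one scalar per time step by two
stacked 128-unit LSTM layers (1000 time steps). The stacked output
(1000 × 128) is flattened and reduced by a fully connected layer to 1000,
reshaped, and mapped by a second fully connected layer to the 500-sample
frame with a tanh output. Batch normalization sits *before* each
leaky-ReLU activation (slope 1e-4) and dropout 0.5 follows, on the LSTM
outputs and the first fully connected layer. The LSTM cell is the
peephole variant — input, forget and output gates receive the previous
cell state through diagonal peephole weights; the candidate does not —
with zero initial state per sequence and no statefulness across batches.

Because the intermediate head sizes are not dictated by the architecture's
narrative beyond "fully connected, reshape, fully connected", they are
spec fields (`fc1_units`, default = `timesteps`) so alternatives remain
testable.

**Critic.** The 500-sample input passes a fully connected layer to 256,
is reshaped to a one-channel map, and runs through four convolutions
(kernel 3, stride 2, "same"-style padding 1) with 8/16/32/64 filters,
halving the length to 128/64/32/16 — leaving the documented 16 × 64
feature map — followed by a fully connected scalar head. Each convolution
is followed by batch normalization, dropout 0.5 and leaky-ReLU 1e-4.
The head is a sigmoid probability under the cross-entropy loss; under the
Wasserstein losses the default is a linear score, because a sigmoid bounds
the critic and collapses the Wasserstein gradient. Both heads are exposed
(`final_activation`) and tested. Batch normalization in the critic is kept
for architectural fidelity even though WGAN-GP practice often omits it; a
`batchnorm = FALSE` switch exists for ablation.

## Losses and training

Three variants are implemented: `bce` (the classic minimax cross-entropy),
`wgan` (`mean D(fake) − mean D(real)` for the critic, `−mean D(fake)` for
the generator) and `wgan_gp`, which adds
`λ · mean((‖∇x D(x̂)‖₂ − 1)²)` with `λ = 10`. The penalty is evaluated at
interpolates `x̂ = ε·real + (1−ε)·fake` (ε uniform per sample), the
standard choice of the gradient-penalty method; a `fake`-only sampling
mode reproduces the objective exactly as printed in some descriptions,
for comparison.

Training follows the two-time-scale schedule: five critic optimizer steps
per generator step (counted in steps, not epochs), Adam with learning
rate 0.001 and betas (0.5, 0.9) — the description only bounds the betas
by [0.5, 0.9], so the conventional GAN endpoints are the default and both
are config fields — batch 64, and a step scheduler that halves the
learning rate every 50 epochs (`lr(e) = 0.001 · 0.5^⌊e/50⌋`). "Epoch"
means a full pass over the shuffled training set; real batches are drawn
without replacement within an epoch. Training aborts, rather than
silently continuing, after three consecutive non-finite losses. Every
random draw (shuffles, noise, dropout masks, interpolation ε) flows from
the run seed, so two runs with the same configuration are bit-identical.

### Differentiation machinery

No automatic-differentiation framework is available to this package, so
it carries a small reverse-mode tape (`R/tape.R`) whose backward pass is
itself built from recorded primitives: running it with `create_graph`
yields a differentiable graph of the gradient, which is exactly what the
gradient penalty needs (the parameter gradient of an input-gradient
norm). Convolutions are expressed as a constant sparse im2col gather plus
a dense matrix product, so they remain twice differentiable; the LSTM
step is fused into a single node with a hand-derived first-order backward
rule — a deliberate asymmetry, since only the critic ever sits under the
penalty. All layer gradients are verified against central differences in
the tests, and the double-backprop path against closed forms.

### Sampling convention

With batch normalization *and* dropout 0.5 inside the generator, the
train-time and eval-time networks differ substantially: BN running
averages systematically shrink sampled amplitudes relative to what the
critic saw during training. `gan_generate()` therefore follows the
classic GAN sampling convention: dropout off, batch normalization using
the statistics of the sampled batch (`bn_mode = "batch"`; single frames
and `bn_mode = "running"` use the running statistics). Sampling remains
deterministic for fixed parameters and noise.

## Similarity metrics

* `rmse()` — root mean square error between paired sequences.
* `dtw_distance()` — dynamic time warping with absolute scalar distance,
  the symmetric step pattern and no warping window (none is specified in
  the method being implemented).
* `frechet_distance()` — the *standard* discrete Fréchet distance: the
  minimum over order-preserving couplings of the maximum pointwise
  Euclidean distance. The printed recurrence in the source description is
  not a well-defined metric; the prose ("considers the location and order
  of the points along the curve") identifies the standard quantity, which
  is what is implemented, as a documented correction. Signals are treated
  as planar curves `(i, x_i)` for the Fréchet distance and as plain value
  sequences for RMSE/DTW.

Both dynamic programs are C++ kernels and are tested against brute-force
enumeration over all monotone paths/couplings for short sequences.
`compare_sets()` aggregates over a `paired_mean` (index-matched pairs,
the default) or `nearest_real_mean` (each generated frame scored against
its nearest real frame) — the aggregation behind published set-level
numbers is unstated, so both are provided and every report names which
was used. `spectrogram()` provides the time–frequency view, normalized so
each column's power sums to the windowed segment energy.

## Compressed-sensing benchmark

Frames are sensed with a sparse binary matrix `phi` (M × N, entries 0/1),
`CR = M/N`; the density is not published, so the default is 4 ones per
column — a common sparse-binary choice — recorded in every result. Ones
are dealt in balanced rounds so row weights stay near-uniform and the
`M = N`, one-one-per-column case degenerates to a permutation (making the
exact-inverse sanity check meaningful). Reconstruction starts from the
pseudoinverse lift `x₀ = phi⁺ y` and is refined by a residual network:
16-channel stem (kernel 3), two residual blocks of six dilated
convolutions (32/64/128/64/32/16 filters, kernels 7/7/5/5/3/3, dilation
2, ELU, "same" padding, identity skip — block input and output are both
16-channel length-500 maps), a one-channel head convolution and a fully
connected output. Reconstructor training is not specified beyond the
architecture: mean-squared error with Adam (lr 0.001) is used and
recorded in the benchmark metadata. Fidelity is `prd()` =
`100 · ‖x̂ − x‖₂ / ‖x‖₂`, lower is better.

`augmentation_benchmark()` trains the reconstructor on real frames plus
0/25/50/75/100% of a generated set for each compression ratio and reports
mean test PRD plus improvement deltas `PRD(none) − PRD(fraction)`,
*truncated* (not rounded) to two decimals — truncation is the convention
that reconciles the published per-cell values with the published prose
ranges, and `reference_prd_tables()` ships those published values so the
delta arithmetic is verifiable exactly (`improvement_summary()`).

## Scale of the shipped experiments

The published experiments train for 1000 epochs on ~29k real frames;
desk-scale checks must be far smaller. The test suite and the acceptance
script use: a reduced adversarial pair (noise/timesteps 100, 16 LSTM
units, frame length 100, critic FC 64) trained 150 epochs on 320
single-band frames — sized so the generator receives exactly one update
per epoch under the 5:1 schedule — and a reduced reconstructor (one
residual block, frame length 100, 15 epochs, 40 real + 40 generated
training frames) at CR = 30%. Stochastic checks are decided by majority
over three fixed seeds. These sizes are the package's chosen study
conditions; the absolute similarity and PRD values they produce are not
comparable to the published full-scale numbers, and are not asserted
against them — only arithmetic identities, architectural contracts,
closed forms and qualitative training behaviour are.

## Known limitations

* The LSTM backward rule is first-order; a gradient penalty *through the
  generator* (not part of this method) would require composing it from
  primitives.
* Pure-R training is orders of magnitude slower than a GPU framework;
  full-scale (1000-epoch, 29k-frame) replication is out of reach here.
* The surrogate corpus does not model artifacts or multi-channel
  structure; conclusions about real EEG require real recordings (GDF
  readers exist elsewhere; this package consumes numeric matrices, CSV
  or NPY).
* The comparison "plain CNN" reconstructor of the published tables is not
  architecturally specified; `cs_resnet_spec(blocks = 0)` (stem + head)
  serves as a clearly-labelled non-faithful stand-in, and replicating
  that table's absolute values is out of scope.
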