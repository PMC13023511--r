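---
title: "Markerless tumor motion forecasting from DRR sequences: models and methods"
author: "drrtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless tumor motion forecasting from DRR sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(drrtrack)
```

## The problem

Thoracic tumors move with breathing, typically by 5-20 mm along the
superior-inferior (SI) axis. Real-time tumor tracking systems adapt the
treatment beam to this motion, but the full chain of acquisition, model
inference and beam adjustment introduces latency of up to several
hundred milliseconds, so the clinically relevant quantity is not the
*current* tumor position but its position a few frames *ahead*. drrtrack
frames this as sequence-to-sequence regression: from a sequence of `N`
past coronal fluoroscopy-like projections (digitally reconstructed
radiographs, DRRs), predict the normalized 3D centre-of-mass position of
the tumor at offsets `0..T` from the last observed frame. Offset 0 is
instantaneous tracking; offsets 1..T are forecasts. At the 5 fps frame
rate used throughout, `T = 5` corresponds to one second ahead.

Because no real 4DCT patient data ships with the package, a synthetic
thorax phantom stands in for the patient: every experiment in the test
suite and the acceptance script is generated, trained and evaluated
end-to-end in code.

## The phantom and its breathing model

`makeAnatomy()` builds a voxelized attenuation volume (mm^-1) with a
soft-tissue body ellipsoid (mu = 0.020), two lung fields (0.005), a
posterior bone column (0.060), mild seeded Gaussian texture in the soft
tissue, and a spherical tumor (0.025) with its binary mask. The volume
is stored decomposed into a static background plus an additive tumor
component so that tumor motion can be simulated by resampling the tumor
component alone.

Breathing displacement follows a Lujan-type waveform per axis,

    A(t) = a * (cos^(2n)(pi * t / tau) - m),   n = 2,

where `a` is the peak-to-peak amplitude, `tau` the respiratory period
and `m = choose(2n, n)/4^n` the waveform mean, so the displacement
oscillates around zero and the reference position `Pref` equals the
session mean. The `cos^4` shape reproduces the characteristic long
exhale plateau and brief inhale excursion of free breathing. The tumor
position is `X(t) = Pref + A(t)` plus, for treatment sessions, a
constant baseline shift (bounded by 5 mm per axis) and a rigid setup
error; optional Gaussian per-frame noise models cycle-to-cycle
variability. Defaults for a "patient" are a 10 / 3 / 2 mm (SI / AP / LR)
amplitude at a 4 s period; treatment sessions default to amplitude
x 1.1, period x 0.95 and 0.3 mm frame noise, emulating inter-session
variability.

A deliberate simplification: the tumor translates rigidly, with
trilinear interpolation and zero padding at the grid edge, while the
surrounding anatomy stays static. Real respiratory motion deforms the
whole thorax (diaphragm, ribs, vessels); deformable motion models are
out of scope, and this is the phantom's main realism gap: a network
trained on the phantom can only exploit the moving tumor itself, not
correlated surrogate structures such as the diaphragm dome.

## DRR formation and preprocessing

`projectBeerLambert()` projects a volume along the anterior-posterior
axis with the absorption-only Beer-Lambert model,

    I(z, x) = I0 * exp( - sum_y mu(z, y, x) * dy ),

a parallel-beam coronal view with `I0 = 1`. Scatter, beam hardening and
detector noise are not modelled. Intensities are min-max normalized to
[0, 1]; by default the statistics are computed globally over all frames
of a sequence rather than per frame, so breathing-induced intensity
modulation survives as a temporal signal (per-frame statistics are a
switch, `normalizeImages(x, stats = "frame")`). `resampleImage()`
rescales with separable bilinear interpolation while preserving the
physical field of view (512 x 512 at 1 mm becomes 64 x 64 at 8 mm), and
`patchify()` cuts frames into P x P tokens, ordered (time, patch row,
patch column) with row-major pixels; `Ntok = W * H / P^2` tokens per
frame, and non-divisible patch sizes are rejected rather than padded.

## Position normalization

Positions are mapped per axis to [-1, 1] over a motion range derived
from the *planning* session:

    Xmax = Pref + (Aplan + margin),  Xmin = Pref - (Aplan + margin)
    Xhat = 2 * (X - Xmin) / (Xmax - Xmin) - 1

with `Pref` the planning mean position, `Aplan` the per-axis maximum
absolute displacement observed during planning, and a 5 mm margin that
absorbs the residual baseline shift expected between planning and
treatment. Without the margin, shifted treatment positions would fall
outside the label distribution the network was trained on. The treatment
amplitude is unknown at inference, so normalization always uses the
planning amplitude. Positions beyond the bounds (drift larger than the
margin) are clipped to [-1, 1] with a warning rather than rejected,
since inference must not abort mid-treatment; this out-of-range policy
is the package's own choice.

`makeWindows()` builds supervised samples with stride 1: window `i`
pairs frames `[i, i+N)` with the normalized positions at offsets `0..T`
from frame `i+N-1`, giving `L - N - T + 1` windows from `L` frames. The
decoder therefore emits `T + 1` positions, reconciling the forecasting
horizon `T` with the tracking mode `T = 0` under a single convention.

## Architectures

Three interchangeable architectures expose the same
`(past frames) -> (T+1) x 3` contract.

**Encoder-decoder trajectory ViT** (`buildTrajViViT()`): the encoder
embeds each P x P patch with a single linear map, scales embeddings by
`sqrt(d_model)` so the additive positional encoding does not dominate
the image signal, adds a factorized spatio-temporal sinusoidal encoding
(temporal sinusoid on the first half of the channels, spatial on the
second half, so every frame/patch pair is distinct), and applies a stack
of pre-layer-norm transformer blocks closed by a final norm. Pre-LN is
the ViT convention and keeps gradient scales stable at the small step
budgets used here. The decoder embeds 3D coordinates with a linear map,
adds a temporal sinusoid, and alternates causally masked self-attention,
cross-attention to the encoder memory, and a feed-forward block; a
linear head emits one 3-vector per step. Decoding starts from a
*learned start-of-sequence (SOS) vector*: in the markerless setting no
past positions are observed, so the first decoder query carries no
coordinate information — this choice is deliberate and visible
(`params$sos`). Defaults follow the study configuration: 6 + 6 layers,
`d_model = 512`, 8 heads, feed-forward width 2048, dropout 0.1 on
embeddings and sub-layer outputs.

Training uses full teacher forcing (the decoder sees ground-truth
previous positions, shifted right behind the SOS token); inference is
autoregressive, feeding each predicted position back. The causal mask
makes teacher-forced predictions at step `k` exactly invariant to inputs
beyond `k`, which the tests assert bit-for-bit.

**Encoder-only ViT** (`buildEncoderViT()`): the same encoder plus a
learned CLS token; a linear head regresses all `3 * (T+1)` outputs from
the CLS representation in one shot.

**ConvLSTM tracker** (`buildConvLSTM()`): stacked convolutional LSTM
layers (default two layers of 16 channels, 3 x 3 kernels, forget-gate
bias 1) run over the frame sequence; the final hidden state is globally
average-pooled and mapped linearly to all outputs.

All three are implemented directly in R matrix algebra with
hand-derived backward passes (the environment provides no deep-learning
framework, and the forecasting machinery is the package's core, so it
is first-party code). Correctness is enforced by finite-difference
gradient checks over all three architectures in the test suite, plus
exact algebraic oracles (parameter-count arithmetic, closed-form
ConvLSTM gate updates, teacher-forcing vs. step-by-step equivalence).

## Training

`trainModel()` minimizes the RMSE loss — the square root of the mean
squared error over batch, forecast steps and coordinates, in normalized
units — with Adam (beta = 0.9 / 0.999, eps = 1e-8, no weight decay).
The learning rate follows a one-epoch linear warmup from peak/100 to
the peak, then a single half-cosine anneal back to peak/100 with no
restarts; `lrAt()` is exact at the three boundary steps and continuous
at the warmup joint. Full-scale defaults are 25 epochs, batch 12, and
peak learning rates of 5e-5 for patient-specific (PS) training and 1e-4
for multi-patient (MP) training. Training is bit-reproducible under a
seed (initialization, shuffling and dropout are all seeded).

**Checkpoint selection.** Teacher forcing conditions the decoder on
ground-truth previous positions, so the teacher-forced loss is nearly
blind to how a checkpoint behaves when fed its own predictions: the
autoregressive rollout quality can swing substantially between adjacent
epochs while the training loss is flat — the train/inference
discrepancy inherent to teacher forcing. `trainModel()` therefore
records, once per epoch, the autoregressive RMSE on a fixed, evenly
spaced subset of up to 12 training windows (`history$arLoss`) and
returns as `bestModel` the checkpoint minimizing it; `model` is the
last epoch. All evaluation harnesses in the package use the best
checkpoint, which is standard early-stopping practice applied in the
deployment regime.

`trainMultiPatient()` pools the windows of all patients except a
held-out one, each patient normalized with its own planning bounds
(normalization is defined per patient), and tags the resulting model
with the held-out identity for leakage checks.

**LoRA fine-tuning** (`finetuneLoRA()`): rank-r adapters `(alpha/r) A B`
are added to the query and value projections of every attention block
(encoder self-attention, decoder self- and cross-attention), with `A`
Glorot-initialized and `B = 0`, so the adapted model is bit-identical
to the frozen base until the first optimizer step. Only adapters train,
at a constant learning rate of 1e-2. Defaults the package chooses where
the method leaves them open: rank 8, alpha = rank, 50 passes over the
shot set.

## Evaluation

`rmseMM()` denormalizes predictions and truth back to millimetres and
reports per-axis RMSE plus a pooled value defined as
`sqrt(mean(per-axis MSE))`, so `pooled^2` is exactly the mean of the
per-axis MSEs; how published per-axis values aggregate into a pooled
column is generally ambiguous, so the package fixes and documents this
one definition. `horizonSweep()` performs one autoregressive rollout
per window and reports RMSE separately per offset (evaluation at
horizon T uses the offset-T prediction only). `persistenceSweep()` is
the naive baseline that carries the last observed position forward.

`pairedCompare()` is a two-sided Wilcoxon signed-rank test on paired
pooled-RMSE differences. Zero differences are dropped (identical inputs
give p = 1); for up to 25 pairs the exact null distribution is computed
by dynamic programming over doubled signed ranks, which remains valid
under ties where the base implementation falls back to an
approximation; beyond 25 pairs the normal approximation with a tie
correction is used. Five replicate seeds per configuration is the
default experimental unit.

`sweepSpatial()` and `sweepTemporal()` are the design-sweep harnesses:
the first trains one seeded model per (resolution W, patch P)
configuration on identical data, keeping the token count controlled
through P; the second varies the input sequence length N and reports
each configuration's relative RMSE deviation,
`100 * (RMSE_N - min RMSE) / min RMSE`, so the best N sits at exactly
0 %.

## The scaled-down study harnesses

Training a 512-dimensional, 6+6-layer transformer on 10,000 DRRs is a
GPU-scale undertaking. The package's self-contained studies
(`studyLearningSanity()`, `studyFinetuneBenefit()`,
`studyTestSetConstruction()`) use a scaled-down configuration chosen
once: 32 x 32 frames with 16-pixel patches (4 tokens per frame),
`d_model = 64`, 4 heads, feed-forward 128, 2 + 2 layers, N = 8 past
frames, horizon T = 5, and a peak learning rate of 3e-3 — a standard
choice for a transformer this small, where the full-scale rates are too
conservative to move the weights in a few hundred steps. Problem sizes:
a 40^3-voxel phantom at 3 mm, 200 training windows, 25 epochs, batch
12 for the learning-sanity study; three training patients plus one
held-out patient (23 s sessions each), a 4 mm SI baseline shift at
treatment, 20 annotated shots and a 20 s test sequence for the
fine-tuning study; a 64^3-voxel phantom at 2 mm for the corpus
construction study (10 treatment sequences of 20 s at 5 fps = 1000
frames of 64 x 64 pixels). Each study runs in minutes on one CPU.

**What desk scale does and does not show.** At these sizes the
encoder-decoder model reliably learns the motion *statistics* of the
phantom — the mean position, the per-axis amplitude structure, and
stable autoregressive continuation — which is enough to beat the
persistence baseline at the one-second horizon, where persistence
degrades sharply on a 4 s cycle. It does not yet exploit the full
image-conditioned tracking signal: a linear ridge probe on the raw
pixels recovers the instantaneous SI position to well under a
millimetre, so the information is present in the DRRs, but
gradient-based training needs far more data and steps than the
desk-scale budget provides before the attention pathway amplifies the
small moving-tumor component against the static anatomy. Passing the
scaled-down studies therefore demonstrates a correct, trainable
pipeline and the qualitative strategy ordering (few-shot adaptation
helps a shifted patient; persistence loses at long horizons), not
clinical-grade tracking accuracy. The fine-tuning study isolates
adaptation randomness: the MP model is pre-trained once per base seed
and five adapter seeds are compared against its frozen performance.

## Numerical choices and degenerate inputs

* Layer norm uses population variance with eps = 1e-5; softmax rows are
  max-shifted; masked attention scores are set to -Inf so causality is
  exact, not approximate.
* Trilinear tumor shifts use zero padding; a shift that would push the
  mask's bounding box outside the grid raises a geometry error rather
  than silently truncating the tumor.
* Min-max normalization of a constant image returns all zeros.
* A warmup of a single optimizer step returns the floor value peak/100
  (a degenerate schedule; the ramp needs at least two steps).
* `resampleImage()` to the identical size is exact to machine
  precision; interpolation positions are clamped at the border (edge
  pixel replication).
* Checkpoints embed the configuration and a 32-bit rolling hash of its
  YAML serialization; loading verifies the hash and, optionally, an
  expected configuration.

## Known limitations

* Rigid tumor translation only; no deformable anatomy, no surrogate
  structures, no articulated ribcage.
* Parallel-beam projection without scatter or detector physics.
* Desk-scale training budgets (see above); the full-scale configuration
  is the default but is not exercised by the test suite.
* Single coronal view; biplane inputs and uncertainty estimates are out
  of scope.
* The Wilcoxon comparison assumes paired results aligned on
  (patient, seed); no multi-level modelling of patient heterogeneity.
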