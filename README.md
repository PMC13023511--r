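# drrtrack

Markerless forecasting of respiratory lung-tumor motion from sequences
of digitally reconstructed radiographs (DRRs), for researchers working
on real-time tumor tracking in radiotherapy.

Tumors in the thorax move with breathing, and the tracking chain
(imaging, inference, beam adjustment) is not instantaneous: what the
treatment system needs is the tumor position a few frames *ahead*.
drrtrack frames this as sequence-to-sequence regression. Given `N` past
coronal DRR frames `X = (X_{t-N+1}, ..., X_t)`, an encoder-decoder
vision transformer predicts the tumor centre-of-mass positions
`Y = (Y_t, Y_{t+1}, ..., Y_{t+T})` autoregressively, where offset 0 is
instantaneous tracking and `T = 5` at 5 fps is a one-second forecast.
Positions are normalized per axis to [-1, 1] over the planning motion
range with a 5 mm safety margin,

    Xmax = Pref + (Aplan + 5),   Xmin = Pref - (Aplan + 5),
    Xhat = 2 (X - Xmin) / (Xmax - Xmin) - 1,

so treatment-time baseline shifts stay inside the training
distribution. DRRs are formed with the absorption-only Beer-Lambert
model `I = I0 exp(-∫ mu dy)` projected along the anterior-posterior
axis, min-max normalized per sequence, resampled with a preserved field
of view, and cut into `Ntok = W·H/P²` patch tokens.

The package contains, end to end:

* a synthetic thorax phantom with a Lujan-type `cos⁴` breathing model,
  rigid tumor translation, planning vs. treatment sessions (amplitude /
  period changes, baseline shift, setup error, frame noise) and exact
  analytic ground-truth trajectories;
* Beer-Lambert projection, sequence normalization, field-of-view
  preserving resampling and ViT patch tokenization;
* three forecasting architectures behind one contract — the
  encoder-decoder trajectory ViT (trained with teacher forcing, decoded
  autoregressively from a learned SOS embedding), an encoder-only ViT
  with a CLS token, and a ConvLSTM tracker — implemented in base-R
  matrix algebra with hand-derived backward passes and
  finite-difference-verified gradients;
* training with Adam under a warmup + cosine-annealing schedule, RMSE
  loss over all forecast steps, multi-patient leave-one-out pooling,
  and patient-specific fine-tuning via low-rank adapters (LoRA, rank 8
  on every attention Q/V projection, exact identity at initialization);
* evaluation in millimetres (per-axis and pooled RMSE), autoregressive
  horizon sweeps, a persistence baseline, an exact paired Wilcoxon
  signed-rank comparison, and resolution/patch and sequence-length
  design-sweep harnesses.

See `vignettes/drrtrack-methods.Rmd` for the models, parameter
conventions, numerical choices and limitations.

## Worked example

Simulate a patient, train the scaled-down forecaster on its planning
session, and compare one-second-ahead accuracy against the persistence
baseline on a held-out free-breathing sequence:

```r
library(drrtrack)

anat <- makeAnatomy(c(40, 40, 40), 3, tumorCenter = c(60, 52, 85),
                    tumorRadius = 9, seed = 1)
plan <- sessionSpec("planning", amplitude = c(10, 3, 2), period = 4, seed = 1)
ses  <- makeSessionDRR(anat, plan, duration_s = 43, fps = 5)
bounds <- boundsFromTrajectory(ses$trajectory)
bounds

seq32 <- normalizeImages(resampleImage(ses$drr, 32, 32))
train <- makeWindows(seq32, ses$trajectory, N = 8, T = 5, bounds)
train

cfg <- modelConfig(imageSize = c(32, 32), patchSize = 16, nPastFrames = 8,
                   horizon = 5, dModel = 64, nHeads = 4, dFfn = 128,
                   nEncLayers = 2, nDecLayers = 2)
fit <- trainModel(buildTrajViViT(cfg, seed = 1), train,
                  trainConfig(epochs = 25, batchSize = 12, peakLr = 3e-3, seed = 1))

test <- makeSessionDRR(anat, sessionSpec("planning", amplitude = c(10, 3, 2),
                                         period = 4, seed = 99),
                       duration_s = 20, fps = 5)
testWin <- makeWindows(normalizeImages(resampleImage(test$drr, 32, 32)),
                       test$trajectory, N = 8, T = 5, bounds)
horizonSweep(fit$bestModel, testWin)
persistenceSweep(testWin)
```

which prints (numbers from this exact script):

```
NormalizationBounds (margin 5 mm)
  Pref: 59.94, 52.08, 85.09 mm
  Aplan: 6.31, 1.89, 1.26 mm
  range: 48.64, 45.19, 78.83  ->  71.25, 58.97, 91.35 mm
ForecastSampleSet: 203 windows (N = 8 , T = 5 ) over 215 frames of 32 x 32 px, session planning-1 
  horizon  rmse_si  rmse_ap   rmse_lr     rmse
1       0 3.618536 1.086257 0.7230462 2.220852
2       1 3.617114 1.082114 0.7207633 2.219158
3       2 3.623922 1.083387 0.7179150 2.222756
4       3 3.648575 1.089204 0.7179666 2.237107
5       4 3.656732 1.091872 0.7200309 2.242195
6       5 3.639774 1.090906 0.7326782 2.234192
  horizon  rmse_si   rmse_ap   rmse_lr      rmse
1       0 0.000000 0.0000000 0.0000000 0.0000000
2       1 1.188461 0.3565384 0.2376922 0.7293964
3       2 2.344668 0.7034005 0.4689337 1.4389974
4       3 3.432199 1.0296596 0.6864397 2.1064493
5       4 4.417224 1.3251671 0.8834448 2.7109905
6       5 5.270199 1.5810598 1.0540399 3.2344888
```

Reading the output: the bounds span `Pref ± (Aplan + 5)` mm per axis,
and the two tables report RMSE in millimetres per forecast offset
(0 = tracking, 5 = one second ahead). Persistence is exact at offset 0
by construction and strong at short horizons, but its error grows
steeply along the 4 s breathing cycle (3.23 mm pooled at offset 5); the
trained forecaster is nearly flat across horizons and clearly better
one second ahead (2.23 vs. 3.23 mm here). At this desk
scale the network captures the phantom's motion statistics rather than
full image-conditioned tracking — the vignette discusses exactly what
that distinction means and why it matters for interpreting these
numbers.

A thin command-line wrapper over these functions is installed at
`inst/cli/drrtrack.R` with `phantom`, `project`, `train` and `eval`
subcommands.

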