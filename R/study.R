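# Scaled-down study harnesses: self-contained experiments that exercise
# the full pipeline (phantom -> DRR -> windows -> training -> evaluation)
# at desk scale. Sizes are chosen so each experiment runs in minutes on
# one CPU; the methods vignette discusses what these scales do and do
# not demonstrate.

# shared scaled-down transformer configuration (2+2 layers, d 64,
# 4 heads, FFN 128) on 32 x 32 frames with 16-pixel patches
.study_model_cfg <- function(N = 8, Th = 5) {
  modelConfig(imageSize = c(32, 32), patchSize = 16, nPastFrames = N,
              horizon = Th, dModel = 64, nHeads = 4, dFfn = 128,
              nEncLayers = 2, nDecLayers = 2, dropout = 0.1)
}

# one phantom patient: anatomy, planning session, bounds and training
# windows at 32 x 32
.study_patient <- function(name, tumorCenter, tumorRadius, amplitude,
                           period, seed, duration_s, N = 8, Th = 5) {
  anat <- makeAnatomy(c(40, 40, 40), 3, tumorCenter, tumorRadius,
                      seed = seed)
  plan <- sessionSpec("planning", amplitude = amplitude, period = period,
                      seed = seed)
  ses <- makeSessionDRR(anat, plan, duration_s = duration_s, fps = 5)
  bounds <- boundsFromTrajectory(ses$trajectory)
  sq <- normalizeImages(resampleImage(ses$drr, 32, 32))
  sq@sessionId <- name
  win <- makeWindows(sq, ses$trajectory, N, Th, bounds)
  list(name = name, anat = anat, plan = plan, bounds = bounds, win = win)
}

# pooled RMSE (mm) of autoregressive forecasts over all offsets 0..T
.study_pooled_rmse <- function(model, win) {
  Th <- win@horizon
  nw <- length(win)
  preds <- array(0, c(nw, Th + 1, 3))
  for (i in seq_len(nw))
    preds[i, , ] <- forecastAutoregressive(model, sampleFrames(win, i), Th)
  rmseMM(matrix(preds, ncol = 3), matrix(win@targets, ncol = 3),
         win@bounds)$pooled
}

#' Learning-sanity study: trained forecaster vs. persistence
#'
#' Trains the scaled-down encoder-decoder ViT on a noiseless phantom
#' (4 s period, 10 mm SI amplitude, N = 8 past frames, horizon T = 5,
#' 200 training windows, 25 epochs) once per replicate seed and compares
#' its offset-5 (one-second-ahead) RMSE against the persistence baseline
#' on a held-out noiseless free-breathing sequence.
#'
#' @param seed base seed; replicate r uses seed + r.
#' @param nSeeds number of replicate seeds (default 5).
#' @param epochs training epochs per replicate (default 25).
#' @param nTrainWindows training windows per replicate (default 200).
#' @return a list: \code{persistence} (offset-5 persistence RMSE, mm),
#'   \code{results} (data.frame seed / rmse5 / beats), \code{wins}
#'   (number of seeds beating persistence), and \code{sweepLast} (the
#'   last replicate's full horizon sweep).
#' @export
studyLearningSanity <- function(seed = 1, nSeeds = 5, epochs = 25,
                                nTrainWindows = 200) {
  N <- 8; Th <- 5
  # 200 windows need 200 + N + T - 1 = 212 frames = 42.4 s at 5 fps
  dur <- (nTrainWindows + N + Th - 1) / 5 + 0.6
  pat <- .study_patient("sanity", c(60, 52, 85), 9, c(10, 3, 2), 4,
                        seed = seed, duration_s = dur, N = N, Th = Th)
  train <- subsetWindows(pat$win, seq_len(nTrainWindows))
  testSes <- makeSessionDRR(pat$anat,
                            sessionSpec("planning", amplitude = c(10, 3, 2),
                                        period = 4, seed = seed + 900),
                            duration_s = 20, fps = 5)
  testSq <- normalizeImages(resampleImage(testSes$drr, 32, 32))
  testSq@sessionId <- "sanity-test"
  testWin <- makeWindows(testSq, testSes$trajectory, N, Th, pat$bounds)
  pers <- persistenceSweep(testWin)
  cfg <- .study_model_cfg(N, Th)
  rows <- list(); sweepLast <- NULL
  for (r in seq_len(nSeeds)) {
    s <- seed + r
    fit <- trainModel(buildTrajViViT(cfg, seed = s), train,
                      trainConfig(epochs = epochs, batchSize = 12,
                                  peakLr = 3e-3, seed = s))
    sw <- horizonSweep(fit$bestModel, testWin)
    sweepLast <- sw
    rows[[r]] <- data.frame(seed = s, rmse5 = sw$rmse[6],
                            beats = sw$rmse[6] < pers$rmse[6])
  }
  results <- do.call(rbind, rows)
  list(persistence = pers$rmse[6], results = results,
       wins = sum(results$beats), sweepLast = sweepLast)
}

#' Fine-tuning-benefit study: 20-shot LoRA vs. frozen multi-patient model
#'
#' Pre-trains a multi-patient model on three phantom patients, holds out
#' a fourth, and confronts it with the held-out patient's treatment
#' sessions carrying a 4 mm superior-inferior baseline shift. The frozen
#' model is then adapted with 20 annotated treatment windows via
#' low-rank adapters (rank 8, constant learning rate 1e-2) once per
#' replicate seed, and pooled RMSE on a separate treatment sequence is
#' compared before and after adaptation.
#'
#' For reference, the same shot budget is also spent once on a
#' patient-specific model trained from scratch (random initialization,
#' identical epochs over the shots). Note that under a baseline shift
#' the frozen multi-patient model carries a systematic bias, so any
#' patient-adapted model -- including the few-shot from-scratch one --
#' can overtake it; the from-scratch figure is a descriptive reference
#' point, not a strategy ordering.
#'
#' @param seed base seed; adapters of replicate r use seed + r.
#' @param nSeeds number of replicate fine-tuning seeds (default 5).
#' @param epochs multi-patient training epochs (default 25).
#' @param nShots annotated treatment windows for adaptation (default 20).
#' @return a list: \code{frozen} (pooled RMSE of the frozen model, mm),
#'   \code{results} (data.frame seed / rmse / improves), \code{wins}
#'   (seeds where adaptation lowers the RMSE), \code{rmseScratch}
#'   (pooled RMSE of the single from-scratch reference model), and
#'   \code{mpModel}.
#' @export
studyFinetuneBenefit <- function(seed = 1, nSeeds = 5, epochs = 25,
                                 nShots = 20) {
  N <- 8; Th <- 5
  cohort <- list(
    list(ctr = c(60, 52, 85), r = 9,  amp = c(10, 3, 2),    per = 4.0),
    list(ctr = c(66, 48, 32), r = 8,  amp = c(8, 2.5, 1.5), per = 3.6),
    list(ctr = c(54, 56, 80), r = 10, amp = c(12, 4, 2.5),  per = 4.4),
    list(ctr = c(62, 50, 36), r = 9,  amp = c(9, 3, 2),     per = 3.8))
  names(cohort) <- paste0("p", seq_along(cohort))
  pats <- Map(function(nm, p, i)
    .study_patient(nm, p$ctr, p$r, p$amp, p$per, seed = seed + i,
                   duration_s = 23, N = N, Th = Th),
    names(cohort), cohort, seq_along(cohort))
  held <- "p1"
  mp <- trainMultiPatient(lapply(pats, `[[`, "win"), held,
                          buildTrajViViT(.study_model_cfg(N, Th),
                                         seed = seed),
                          trainConfig(epochs = epochs, batchSize = 12,
                                      peakLr = 3e-3, seed = seed))
  hp <- pats[[held]]
  mkTreat <- function(sd, dur, id) {
    spec <- treatmentSpec(hp$plan, baselineShift = c(4, 0, 0),
                          noiseSd = 0.3, seed = sd)
    ses <- makeSessionDRR(hp$anat, spec, duration_s = dur, fps = 5)
    sq <- normalizeImages(resampleImage(ses$drr, 32, 32))
    sq@sessionId <- id
    makeWindows(sq, ses$trajectory, N, Th, hp$bounds)
  }
  # shots need nShots + N + T - 1 frames
  shotWin <- subsetWindows(mkTreat(seed + 50, (nShots + N + Th - 1) / 5 + 0.6,
                                   "p1-shots"), seq_len(nShots))
  testWin <- mkTreat(seed + 60, 20, "p1-test")
  mpBest <- mp$bestModel
  frozen <- .study_pooled_rmse(mpBest, testWin)
  rows <- list()
  for (r in seq_len(nSeeds)) {
    s <- seed + r
    ft <- finetuneLoRA(mpBest, shotWin,
                       loraConfig(rank = 8, epochs = 50, seed = s))
    rmse <- .study_pooled_rmse(ft$bestModel, testWin)
    rows[[r]] <- data.frame(seed = s, rmse = rmse, improves = rmse < frozen)
  }
  results <- do.call(rbind, rows)
  # single few-shot from-scratch reference under the same budget
  ps <- trainModel(buildTrajViViT(.study_model_cfg(N, Th), seed = seed + 1),
                   shotWin,
                   trainConfig(epochs = 50, batchSize = min(12L, nShots),
                               peakLr = 3e-3, seed = seed + 1))
  rmseScratch <- .study_pooled_rmse(ps$bestModel, testWin)
  list(frozen = frozen, results = results, wins = sum(results$improves),
       rmseScratch = rmseScratch, mpModel = mpBest)
}

#' Test-set construction study: frame counts of the evaluation protocol
#'
#' Generates the full evaluation corpus of 10 free-breathing treatment
#' sequences of 20 s at 5 fps from one phantom and returns the frame
#' counts, together with the number of frames spanned by one 4 s
#' respiratory cycle at that frame rate.
#'
#' @param seed base seed; sequence k uses seed + k.
#' @param gridShape phantom grid (default 64^3 voxels at 2 mm).
#' @param spacing voxel size in mm.
#' @return a list: \code{framesPerSequence} (integer(10)),
#'   \code{totalFrames}, \code{framesPerCycle}, and \code{drrSize}
#'   (pixel dimensions of the projected frames).
#' @export
studyTestSetConstruction <- function(seed = 1, gridShape = c(64, 64, 64),
                                     spacing = 2) {
  extent <- (gridShape - 1) * spacing
  anat <- makeAnatomy(gridShape, spacing,
                      tumorCenter = extent * c(0.5, 0.45, 0.72),
                      tumorRadius = 0.1 * extent[1], seed = seed)
  plan <- sessionSpec("planning", amplitude = c(10, 3, 2), period = 4,
                      seed = seed)
  counts <- integer(10)
  drrSize <- NULL
  for (k in 1:10) {
    spec <- treatmentSpec(plan, baselineShift = c(2, -1, 1),
                          noiseSd = 0.3, seed = seed + k)
    ses <- makeSessionDRR(anat, spec, duration_s = 20, fps = 5)
    counts[k] <- length(ses$drr)
    drrSize <- dim(frames(ses$drr))[1:2]
  }
  list(framesPerSequence = counts, totalFrames = sum(counts),
       framesPerCycle = as.integer(round(plan@period * 5)),
       drrSize = drrSize)
}
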