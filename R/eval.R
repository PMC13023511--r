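# Evaluation: RMSE in millimetres (per axis and pooled), autoregressive
# horizon sweeps, the persistence baseline, exact paired Wilcoxon
# signed-rank comparison, and the spatial / temporal design-sweep
# harnesses.

#' RMSE in millimetres between normalized trajectories
#'
#' Denormalizes both trajectories with the given bounds and computes the
#' per-axis root-mean-square error over all evaluated time points. The
#' pooled value is the square root of the mean per-axis MSE, so
#' pooled^2 = mean(axis MSEs) exactly.
#'
#' @param predNorm,trueNorm n x 3 matrices of normalized positions.
#' @param bounds the \linkS4class{NormalizationBounds} of the patient.
#' @return a list with \code{perAxis} (named numeric(3): si, ap, lr) and
#'   \code{pooled}, both in mm.
#' @export
rmseMM <- function(predNorm, trueNorm, bounds) {
  predNorm <- rbind(predNorm); trueNorm <- rbind(trueNorm)
  if (!identical(dim(predNorm), dim(trueNorm)))
    stop("prediction and truth lengths differ")
  P <- denormalizePosition(predNorm, bounds)
  X <- denormalizePosition(trueNorm, bounds)
  mse <- colMeans((P - X)^2)
  list(perAxis = stats::setNames(sqrt(mse), c("si", "ap", "lr")),
       pooled = sqrt(mean(mse)))
}

#' Autoregressive RMSE per forecast horizon
#'
#' Performs one autoregressive rollout per window and reports the RMSE
#' separately for each offset 0..Tmax (offset 0 is instantaneous
#' tracking; offsets are not averaged together).
#'
#' @param model a \linkS4class{ForecastModel}.
#' @param samples a \linkS4class{ForecastSampleSet} built with horizon
#'   >= Tmax.
#' @param Tmax largest horizon to evaluate (default: the set's horizon).
#' @return a data.frame with columns horizon, rmse_si, rmse_ap, rmse_lr,
#'   rmse (all mm).
#' @export
horizonSweep <- function(model, samples, Tmax = samples@horizon) {
  if (samples@horizon < Tmax)
    stop("samples were built with horizon ", samples@horizon,
         " < Tmax = ", Tmax)
  nwin <- length(samples)
  preds <- array(0, c(nwin, Tmax + 1, 3))
  for (i in seq_len(nwin))
    preds[i, , ] <- forecastAutoregressive(model, sampleFrames(samples, i),
                                           Tmax)[seq_len(Tmax + 1), ]
  .offset_rmse(preds, samples, Tmax)
}

.offset_rmse <- function(preds, samples, Tmax) {
  out <- do.call(rbind, lapply(0:Tmax, function(h) {
    r <- rmseMM(matrix(preds[, h + 1, ], ncol = 3),
                matrix(samples@targets[, h + 1, ], ncol = 3),
                samples@bounds)
    data.frame(horizon = h, rmse_si = r$perAxis[["si"]],
               rmse_ap = r$perAxis[["ap"]], rmse_lr = r$perAxis[["lr"]],
               rmse = r$pooled)
  }))
  rownames(out) <- NULL
  out
}

#' Persistence baseline per forecast horizon
#'
#' Carries the true position at the last observed frame (offset 0)
#' forward unchanged for every offset, the standard naive forecaster.
#'
#' @param samples a \linkS4class{ForecastSampleSet}.
#' @param Tmax largest horizon to evaluate (default: the set's horizon).
#' @return a data.frame as in \code{\link{horizonSweep}}.
#' @export
persistenceSweep <- function(samples, Tmax = samples@horizon) {
  if (samples@horizon < Tmax)
    stop("samples were built with horizon ", samples@horizon,
         " < Tmax = ", Tmax)
  nwin <- length(samples)
  preds <- array(0, c(nwin, Tmax + 1, 3))
  for (h in 0:Tmax) preds[, h + 1, ] <- samples@targets[, 1, ]
  .offset_rmse(preds, samples, Tmax)
}

#' Exact paired Wilcoxon signed-rank comparison
#'
#' Two-sided Wilcoxon signed-rank test on paired pooled-RMSE differences
#' across (patient, seed) pairs. Zero differences are dropped (Wilcoxon
#' convention; identical inputs give p = 1); the exact null distribution
#' is computed by dynamic programming over signed average ranks (valid
#' under ties) for n <= 25 pairs, falling back to the normal
#' approximation beyond that.
#'
#' @param a,b numeric vectors of paired results aligned on the same
#'   (patient, seed) keys, or data.frames with columns \code{patient},
#'   \code{seed} and \code{rmse}.
#' @return a list: \code{statistic} (V, sum of positive signed ranks),
#'   \code{p.value}, \code{medianDiff} (median of a - b) and \code{n}
#'   (non-zero pairs).
#' @export
pairedCompare <- function(a, b) {
  if (is.data.frame(a)) {
    if (!identical(a[c("patient", "seed")], b[c("patient", "seed")]))
      stop("results are not aligned on (patient, seed) keys")
    a <- a$rmse; b <- b$rmse
  }
  if (length(a) != length(b)) stop("paired results must have equal length")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- a - b
  md <- stats::median(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p.value = 1, medianDiff = md, n = 0L))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution of V by convolution over doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    pmf <- c(1, numeric(maxs))
    for (rr in r2) {
      shifted <- c(numeric(rr), pmf[seq_len(maxs + 1 - rr)])
      pmf <- (pmf + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    pLo <- sum(pmf[seq_len(v2 + 1)])
    pHi <- sum(pmf[(v2 + 1):(maxs + 1)])
    p <- min(1, 2 * min(pLo, pHi))
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = V, p.value = p, medianDiff = md, n = n)
}

#' Relative RMSE deviation from the best configuration
#'
#' \code{100 * (rmse - min(rmse)) / min(rmse)} per entry; the best
#' configuration has deviation exactly 0.
#'
#' @param rmse numeric vector of RMSEs (non-empty, positive).
#' @return numeric vector of percentage deviations.
#' @export
relativeRmseDeviation <- function(rmse) {
  if (length(rmse) == 0) stop("rmse must be non-empty")
  m <- min(rmse)
  100 * (rmse - m) / m
}

# shared train-and-evaluate step for the design sweeps
.sweep_fit_eval <- function(trainSeq, trainTraj, testSeq, testTraj, bounds,
                            W, P, N, Th, cfgBase, trainCfg, seed) {
  trS <- resampleImage(trainSeq, W, W)
  teS <- resampleImage(testSeq, W, W)
  trS <- normalizeImages(trS); teS <- normalizeImages(teS)
  mcfg <- modelConfig(imageSize = c(W, W), patchSize = P, nPastFrames = N,
                      horizon = Th, dModel = cfgBase$dModel,
                      nHeads = cfgBase$nHeads, dFfn = cfgBase$dFfn,
                      nEncLayers = cfgBase$nEncLayers,
                      nDecLayers = cfgBase$nDecLayers,
                      dropout = cfgBase$dropout)
  trW <- makeWindows(trS, trainTraj, N, Th, bounds)
  teW <- makeWindows(teS, testTraj, N, Th, bounds)
  tc <- trainCfg; tc$seed <- trainCfg$seed + seed
  model <- buildTrajViViT(mcfg, seed = tc$seed)
  fit <- trainModel(model, trW, tc)
  sw <- horizonSweep(fit$bestModel, teW, Th)
  sw$rmse[sw$horizon == Th]
}

#' Spatial design sweep: image resolution vs. patch size
#'
#' Trains and evaluates one seeded model per (W, P) configuration on the
#' same data, holding the token count controllable through P, and
#' reports the RMSE grid at the configured horizon.
#'
#' @param trainData,testData lists with elements \code{seq} (a raw
#'   \linkS4class{DRRSequence}) and \code{traj} (L x 3 mm trajectory).
#' @param bounds the patient's \linkS4class{NormalizationBounds}.
#' @param configs list of \code{c(W, P)} pairs (square images).
#' @param seeds integer vector of replicate seeds.
#' @param N past frames; \code{Th} horizon.
#' @param Th forecast horizon.
#' @param cfgBase a \code{\link{modelConfig}} supplying the transformer
#'   dimensions.
#' @param trainCfg a \code{\link{trainConfig}}.
#' @return a data.frame (W, P, ntok, seed, rmse).
#' @export
sweepSpatial <- function(trainData, testData, bounds, configs, seeds = 1,
                         N = 8, Th = 5, cfgBase = modelConfig(),
                         trainCfg = trainConfig()) {
  rows <- list()
  for (cf in configs) {
    W <- cf[1]; P <- cf[2]
    ntok <- tokenCount(W, W, P)
    for (s in seeds) {
      r <- .sweep_fit_eval(trainData$seq, trainData$traj, testData$seq,
                           testData$traj, bounds, W, P, N, Th,
                           cfgBase, trainCfg, s)
      rows[[length(rows) + 1]] <-
        data.frame(W = W, P = P, ntok = ntok, seed = s, rmse = r)
    }
  }
  do.call(rbind, rows)
}

#' Temporal design sweep: input sequence length
#'
#' Trains and evaluates one model per candidate N on the same data and
#' reports each configuration's RMSE together with its relative
#' deviation (percent) from the best-performing N.
#'
#' @param Nvalues integer vector of candidate sequence lengths.
#' @inheritParams sweepSpatial
#' @param W image size; \code{P} patch size.
#' @param P patch size.
#' @return a data.frame (N, rmse, deviationPct).
#' @export
sweepTemporal <- function(Nvalues, trainData, testData, bounds, W = 64,
                          P = 32, Th = 5, cfgBase = modelConfig(),
                          trainCfg = trainConfig()) {
  if (length(Nvalues) == 0) stop("Nvalues must be non-empty")
  rmse <- vapply(Nvalues, function(N)
    .sweep_fit_eval(trainData$seq, trainData$traj, testData$seq,
                    testData$traj, bounds, W, P, N, Th, cfgBase,
                    trainCfg, 0), numeric(1))
  data.frame(N = Nvalues, rmse = rmse,
             deviationPct = relativeRmseDeviation(rmse))
}
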