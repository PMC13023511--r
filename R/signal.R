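# Tumor-position normalization and supervised forecasting-window assembly.
#
# The tumor position decomposes as X(t) = Pref + A(t): a breathing
# displacement around a reference position. Positions are mapped per axis
# to [-1, 1] over a motion range built from the planning session with a
# safety margin, so treatment positions affected by residual baseline
# shifts stay inside the range the network was trained on.

#' Build normalization bounds from a reference position and amplitude
#'
#' \code{Xmax = Pref + (Aplan + margin)}, \code{Xmin = Pref - (Aplan + margin)}
#' per axis. The default 5 mm margin absorbs the maximum residual baseline
#' shift assumed between planning and treatment.
#'
#' @param Pref numeric(3), reference position in mm.
#' @param Aplan numeric(3) or scalar, planning amplitude in mm (>= 0).
#' @param margin safety margin in mm, default 5.
#' @return a \linkS4class{NormalizationBounds}.
#' @examples
#' makeBounds(c(0, 0, 0), c(10, 5, 3))
#' @export
makeBounds <- function(Pref, Aplan, margin = 5) {
  if (length(Aplan) == 1) Aplan <- rep(Aplan, 3)
  if (any(Aplan < 0)) stop("Aplan must be non-negative")
  Pref <- as.numeric(Pref); Aplan <- as.numeric(Aplan)
  new("NormalizationBounds", Pref = Pref, Aplan = Aplan, margin = margin,
      Xmin = Pref - (Aplan + margin), Xmax = Pref + (Aplan + margin))
}

#' Derive bounds from a planning trajectory
#'
#' Pref is the planning mean position; Aplan is the per-axis maximum
#' absolute displacement around Pref observed during the planning session.
#'
#' @param trajectory L x 3 matrix of planning positions in mm.
#' @param margin safety margin in mm, default 5.
#' @return a \linkS4class{NormalizationBounds}.
#' @export
boundsFromTrajectory <- function(trajectory, margin = 5) {
  Pref <- colMeans(trajectory)
  Aplan <- apply(abs(sweep(trajectory, 2, Pref)), 2, max)
  makeBounds(Pref, Aplan, margin)
}

#' Normalize positions to [-1, 1] per axis
#'
#' \code{Xhat = 2 (X - Xmin) / (Xmax - Xmin) - 1}, applied independently
#' per spatial coordinate. Positions outside the bounds (possible when
#' treatment drift exceeds the margin) are clipped to [-1, 1] with a
#' warning rather than rejected, so inference never aborts.
#'
#' @param X numeric(3) or an n x 3 matrix of positions in mm.
#' @param bounds a \linkS4class{NormalizationBounds}.
#' @param clip logical; warn-and-clip out-of-range positions (default TRUE).
#' @return normalized positions, same shape as \code{X}.
#' @export
normalizePosition <- function(X, bounds, clip = TRUE) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  span <- bounds@Xmax - bounds@Xmin
  if (any(span <= 0)) stop("degenerate bounds: Xmax must exceed Xmin")
  Xn <- 2 * sweep(sweep(X, 2, bounds@Xmin), 2, span, "/") - 1
  out <- abs(Xn) > 1 + 1e-12
  if (any(out)) {
    if (!clip) stop("positions outside normalization bounds")
    warning(sprintf("%d position component(s) outside bounds; clipped to [-1, 1]",
                    sum(out)))
    Xn <- pmin(pmax(Xn, -1), 1)
  }
  if (vec) Xn[1, ] else Xn
}

#' Map normalized positions back to mm
#'
#' Inverse of \code{\link{normalizePosition}}:
#' \code{X = Xmin + (Xhat + 1) (Xmax - Xmin) / 2}.
#'
#' @param Xn numeric(3) or an n x 3 matrix of normalized positions.
#' @param bounds a \linkS4class{NormalizationBounds}.
#' @return positions in mm, same shape as \code{Xn}.
#' @export
denormalizePosition <- function(Xn, bounds) {
  vec <- is.null(dim(Xn))
  Xn <- rbind(Xn)
  span <- bounds@Xmax - bounds@Xmin
  if (any(span <= 0)) stop("degenerate bounds: Xmax must exceed Xmin")
  X <- sweep(sweep(Xn + 1, 2, span / 2, "*"), 2, bounds@Xmin, "+")
  if (vec) X[1, ] else X
}

#' Assemble supervised forecasting windows from a DRR sequence
#'
#' Sliding windows of stride 1: sample i pairs frames [i, i+N) with the
#' normalized positions at offsets 0..T from the last observed frame
#' (offset 0 supervises instantaneous tracking). The number of windows is
#' L - N - T + 1 for a sequence of length L.
#'
#' @param drrSeq a normalized \linkS4class{DRRSequence}.
#' @param trajectory L x 3 matrix of true positions in mm, aligned 1:1
#'   with the frames.
#' @param N number of past frames per sample (>= 1).
#' @param T forecast horizon (>= 0); targets cover offsets 0..T.
#' @param bounds the \linkS4class{NormalizationBounds} for the targets.
#' @return a \linkS4class{ForecastSampleSet}.
#' @export
makeWindows <- function(drrSeq, trajectory, N, T, bounds) {
  stopifnot(is(drrSeq, "DRRSequence"), is(bounds, "NormalizationBounds"))
  L <- dim(drrSeq@frames)[3]
  if (nrow(trajectory) != L)
    stop("trajectory must align 1:1 with the frames")
  if (N < 1 || T < 0) stop("need N >= 1 and T >= 0")
  if (L < N + T + 1)
    stop(sprintf("sequence too short: need at least N + T + 1 = %d frames, have %d",
                 N + T + 1, L))
  nwin <- L - N - T + 1
  starts <- seq_len(nwin)
  trajN <- normalizePosition(trajectory, bounds)
  targets <- array(0, c(nwin, T + 1, 3))
  for (i in starts) targets[i, , ] <- trajN[(i + N - 1):(i + N - 1 + T), , drop = FALSE]
  new("ForecastSampleSet", frames = drrSeq@frames, trajectory = trajectory,
      targets = targets, starts = as.integer(starts), nPast = N, horizon = T,
      bounds = bounds, sessionId = drrSeq@sessionId)
}

#' Extract the past-frame stack of one window
#'
#' @param set a \linkS4class{ForecastSampleSet}.
#' @param i window index.
#' @return a (H, W, N) array of frames.
#' @export
sampleFrames <- function(set, i) {
  s <- set@starts[i]
  set@frames[, , s:(s + set@nPast - 1), drop = FALSE]
}

#' Extract the normalized target positions of one window
#'
#' @param set a \linkS4class{ForecastSampleSet}.
#' @param i window index.
#' @return a (T+1) x 3 matrix of normalized positions at offsets 0..T.
#' @export
sampleTargets <- function(set, i) {
  matrix(set@targets[i, , ], ncol = 3)
}

#' Restrict a sample set to a subset of windows
#'
#' @param set a \linkS4class{ForecastSampleSet}.
#' @param idx window indices to keep.
#' @return a \linkS4class{ForecastSampleSet} with the selected windows.
#' @export
subsetWindows <- function(set, idx) {
  set@starts <- set@starts[idx]
  set@targets <- set@targets[idx, , , drop = FALSE]
  set
}
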