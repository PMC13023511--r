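# Synthetic thorax phantom: anatomy, breathing traces, rigid tumor motion,
# and full free-breathing imaging sessions with exact ground-truth
# centre-of-mass trajectories.

# Nominal linear attenuation coefficients (mm^-1), roughly at diagnostic
# X-ray energies: air ~0, inflated lung, soft tissue, cortical bone, and a
# solid tumor slightly denser than soft tissue.
.MU <- c(lung = 0.005, soft = 0.020, bone = 0.060, tumor = 0.025)

#' Construct an AttenuationVolume from raw arrays
#'
#' Wraps a user-supplied attenuation volume and binary tumor mask. The
#' tumor contribution is separated from the background by filling the
#' masked region with the mean attenuation of the voxels immediately
#' surrounding the mask, so that the tumor can later be translated
#' independently of the static anatomy.
#'
#' @param voxels 3D array of linear attenuation coefficients (mm^-1).
#' @param mask 3D logical (or 0/1) array marking the tumor.
#' @param spacing numeric(3), voxel size in mm (SI, AP, LR).
#' @return an \linkS4class{AttenuationVolume}.
#' @export
attenuationVolume <- function(voxels, mask, spacing) {
  mask <- array(as.logical(mask), dim(voxels))
  if (!any(mask)) stop("tumor mask is empty")
  if (min(voxels) < 0) stop("attenuation values must be non-negative")
  shell <- .dilate_mask(mask) & !mask
  fill <- if (any(shell)) mean(voxels[shell]) else mean(voxels[!mask])
  background <- voxels
  background[mask] <- fill
  delta <- array(0, dim(voxels))
  delta[mask] <- voxels[mask] - fill
  new("AttenuationVolume", background = background, tumorDelta = delta,
      mask = mask, spacing = as.numeric(spacing))
}

# 6-connected dilation by one voxel, used to sample the background shell
# around a tumor mask.
.dilate_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift1 <- function(m, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[axis]] <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
    do.call(`[`, c(list(m), src))
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) out <- out | shift1(mask, axis, by)
  out
}

#' Generate a synthetic thorax anatomy with a spherical tumor
#'
#' Builds a simple thorax stand-in: a soft-tissue body ellipsoid containing
#' two low-attenuation lung fields, a high-attenuation posterior spine
#' column, mild seeded soft-tissue texture, and a spherical tumor of
#' intermediate attenuation with its binary mask. The output is
#' deterministic for a fixed seed.
#'
#' @param gridShape integer(3), voxel grid dimensions (SI, AP, LR).
#' @param spacing numeric(3) or scalar, voxel size in mm.
#' @param tumorCenter numeric(3), tumor centre in world mm.
#' @param tumorRadius tumor radius in mm (> 0).
#' @param seed integer seed for the texture.
#' @return an \linkS4class{AttenuationVolume}.
#' @examples
#' vol <- makeAnatomy(c(32, 32, 32), 4, c(70, 60, 40), 10, seed = 1)
#' vol
#' @export
makeAnatomy <- function(gridShape, spacing, tumorCenter, tumorRadius, seed = 1) {
  gridShape <- as.integer(gridShape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spacing <- as.numeric(spacing)
  if (tumorRadius <= 0) stop("tumorRadius must be positive")
  extent <- (gridShape - 1) * spacing
  if (any(tumorCenter - tumorRadius < 0) ||
      any(tumorCenter + tumorRadius > extent))
    stop("tumor sphere does not fit inside the grid")

  # world coordinates of voxel centres, one vector per axis
  w1 <- (seq_len(gridShape[1]) - 1) * spacing[1]
  w2 <- (seq_len(gridShape[2]) - 1) * spacing[2]
  w3 <- (seq_len(gridShape[3]) - 1) * spacing[3]
  c1 <- extent / 2

  # normalized squared ellipsoid coordinate helpers (broadcast over grid)
  A1 <- array(rep(w1, times = gridShape[2] * gridShape[3]), gridShape)
  A2 <- array(rep(rep(w2, each = gridShape[1]), times = gridShape[3]), gridShape)
  A3 <- array(rep(w3, each = gridShape[1] * gridShape[2]), gridShape)

  ell <- function(ctr, semi)
    ((A1 - ctr[1]) / semi[1])^2 + ((A2 - ctr[2]) / semi[2])^2 +
      ((A3 - ctr[3]) / semi[3])^2

  background <- array(0, gridShape)
  body <- ell(c1, extent * c(0.50, 0.42, 0.45)) <= 1
  background[body] <- .MU[["soft"]]
  # two lung fields, offset left/right inside the body
  for (s in c(-1, 1)) {
    lungCtr <- c1 + c(0, -0.05, s * 0.22) * extent
    lung <- ell(lungCtr, extent * c(0.38, 0.28, 0.17)) <= 1 & body
    background[lung] <- .MU[["lung"]]
  }
  # posterior spine column (cylinder along SI)
  spine <- ((A2 - (c1[2] + 0.30 * extent[2]))^2 + (A3 - c1[3])^2) <=
    (0.07 * mean(extent))^2 & body
  background[spine] <- .MU[["bone"]]
  # mild seeded soft-tissue texture
  withr::with_seed(seed, {
    tex <- array(stats::rnorm(prod(gridShape), 0, 0.03 * .MU[["soft"]]), gridShape)
  })
  soft <- body & background == .MU[["soft"]]
  background[soft] <- pmax(background[soft] + tex[soft], 0)

  dist2 <- (A1 - tumorCenter[1])^2 + (A2 - tumorCenter[2])^2 +
    (A3 - tumorCenter[3])^2
  mask <- dist2 <= tumorRadius^2
  if (!any(mask)) stop("tumor mask is empty; radius too small for spacing")
  delta <- array(0, gridShape)
  delta[mask] <- .MU[["tumor"]] - background[mask]
  delta <- pmax(delta, 0)  # tumor never reduces attenuation

  new("AttenuationVolume", background = background, tumorDelta = delta,
      mask = mask, spacing = spacing)
}

#' Sample a quasi-periodic breathing displacement trace
#'
#' Samples a Lujan-type waveform per axis,
#' \code{A(t) = a * (cos^(2n)(pi t / tau) - mean)}, scaled so the
#' peak-to-peak excursion equals the session amplitude, with optional
#' additive Gaussian per-frame noise (the session's \code{noiseSd}). The
#' mean offset makes the trace oscillate around zero, so the reference
#' position equals the session mean.
#'
#' @param spec a \linkS4class{SessionSpec}.
#' @param duration_s trace duration in seconds (> 0).
#' @param fps sampling rate in frames per second (> 0).
#' @param n waveform exponent half-order (cos^(2n)); default 2, giving the
#'   characteristic long exhale / sharp inhale shape.
#' @return a \linkS4class{BreathingTrace} of length \code{round(duration_s * fps)}.
#' @export
breathingTrace <- function(spec, duration_s, fps, n = 2) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fps <= 0) stop("fps must be positive")
  L <- round(duration_s * fps)
  t <- (seq_len(L) - 1) / fps
  base <- cos(pi * t / spec@period)^(2 * n)
  # cos^(2n) lies in [0, 1]; its mean over a period is choose(2n, n)/4^n
  m <- choose(2 * n, n) / 4^n
  A <- outer(base - m, spec@amplitude)
  if (spec@noiseSd > 0) {
    withr::with_seed(spec@seed, {
      A <- A + matrix(stats::rnorm(L * 3, 0, spec@noiseSd), L, 3)
    })
  }
  colnames(A) <- c("si", "ap", "lr")
  new("BreathingTrace", displacements = A, fps = fps, period = spec@period,
      amplitude = spec@amplitude)
}

#' Construct a session specification
#'
#' @param role "planning" or "treatment".
#' @param amplitude numeric(3) or scalar, peak-to-peak breathing amplitude mm.
#' @param period respiratory period in seconds.
#' @param baselineShift numeric(3), residual baseline shift mm (<= 5 per axis).
#' @param setupError numeric(3), rigid setup error mm.
#' @param noiseSd per-frame Gaussian displacement noise sd mm.
#' @param seed integer seed.
#' @return a \linkS4class{SessionSpec}.
#' @export
sessionSpec <- function(role = c("planning", "treatment"),
                        amplitude = c(10, 3, 2), period = 4,
                        baselineShift = c(0, 0, 0), setupError = c(0, 0, 0),
                        noiseSd = 0, seed = 1) {
  role <- match.arg(role)
  if (length(amplitude) == 1) amplitude <- rep(amplitude, 3)
  new("SessionSpec", role = role, amplitude = as.numeric(amplitude),
      period = period, baselineShift = as.numeric(baselineShift),
      setupError = as.numeric(setupError), noiseSd = noiseSd, seed = seed)
}

#' Derive a treatment session from a planning session
#'
#' Treatment sessions default to a mildly larger amplitude (x 1.1), a
#' slightly shorter period (x 0.95) and per-frame displacement noise,
#' emulating inter-session breathing variability; all factors are exposed.
#'
#' @param planning a planning \linkS4class{SessionSpec}.
#' @param amplitudeFactor,periodFactor multiplicative changes.
#' @param baselineShift,setupError numeric(3) offsets in mm.
#' @param noiseSd per-frame noise sd in mm.
#' @param seed integer seed.
#' @return a treatment \linkS4class{SessionSpec}.
#' @export
treatmentSpec <- function(planning, amplitudeFactor = 1.1, periodFactor = 0.95,
                          baselineShift = c(0, 0, 0), setupError = c(0, 0, 0),
                          noiseSd = 0.3, seed = planning@seed + 1000) {
  sessionSpec("treatment",
              amplitude = planning@amplitude * amplitudeFactor,
              period = planning@period * periodFactor,
              baselineShift = baselineShift, setupError = setupError,
              noiseSd = noiseSd, seed = seed)
}

# Trilinear shift of a 3D array by a fractional voxel offset, zero-padded
# outside the grid: out(i) = in(i - s).
.shift3d <- function(arr, svox) {
  f <- floor(svox)
  w <- svox - f
  d <- dim(arr)
  intShift <- function(a, k) {
    # out(i) = a(i - k) for integer k, zero padding
    if (all(k == 0)) return(a)
    out <- array(0, d)
    srcFrom <- pmax(1 - k, 1); srcTo <- pmin(d - k, d)
    if (any(srcFrom > srcTo)) return(out)
    dstFrom <- srcFrom + k; dstTo <- srcTo + k
    out[dstFrom[1]:dstTo[1], dstFrom[2]:dstTo[2], dstFrom[3]:dstTo[3]] <-
      a[srcFrom[1]:srcTo[1], srcFrom[2]:srcTo[2], srcFrom[3]:srcTo[3]]
    out
  }
  out <- array(0, d)
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    wt <- prod(ifelse(c(c1, c2, c3) == 1, w, 1 - w))
    if (wt > 0) out <- out + wt * intShift(arr, as.integer(f + c(c1, c2, c3)))
  }
  out
}

#' Rigidly translate the tumor inside a volume
#'
#' Translates the tumor component and its mask by a 3-vector displacement
#' in mm via trilinear resampling (zero-padded at the grid edge), leaving
#' the background anatomy untouched. The shifted continuous mask is
#' re-binarized at 0.5.
#'
#' @param anatomy an \linkS4class{AttenuationVolume}.
#' @param displacement numeric(3), displacement in mm (SI, AP, LR).
#' @return a new \linkS4class{AttenuationVolume}.
#' @export
applyMotion <- function(anatomy, displacement) {
  displacement <- as.numeric(displacement)
  if (all(displacement == 0)) return(anatomy)
  svox <- displacement / anatomy@spacing
  d <- dim(anatomy@background)
  idx <- which(anatomy@mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min) + svox
  hi <- apply(idx, 2, max) + svox
  if (any(lo < 1 - 1e-9) || any(hi > d + 1e-9))
    stop("displacement pushes the tumor outside the grid")
  newDelta <- .shift3d(anatomy@tumorDelta, svox)
  newMask <- .shift3d(anatomy@mask + 0, svox) >= 0.5
  new("AttenuationVolume", background = anatomy@background,
      tumorDelta = newDelta, mask = newMask, spacing = anatomy@spacing)
}

#' Centre of mass of a binary mask
#'
#' Unweighted centroid of the masked voxel centres in world mm
#' (world = 0-based index times spacing).
#'
#' @param mask 3D logical (or 0/1) array.
#' @param spacing numeric(3) or scalar, voxel size in mm.
#' @return numeric(3), the centroid in mm (SI, AP, LR).
#' @export
centerOfMass <- function(mask, spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  unname((colMeans(idx) - 1) * spacing)
}

#' Simulate a free-breathing imaging session
#'
#' Applies the session's constant offset (baseline shift + setup error)
#' plus the frame-by-frame breathing displacement to the tumor, returning
#' the moving-tumor volumes and the exact analytic ground-truth trajectory
#' \code{X(t) = Pref + baselineShift + setupError + A(t)} (the trajectory
#' is constructed, not re-measured from voxels).
#'
#' @param anatomy an \linkS4class{AttenuationVolume}.
#' @param spec a \linkS4class{SessionSpec}.
#' @param duration_s session duration in seconds.
#' @param fps frame rate (default 5 fps, the fluoroscopy rate).
#' @param volumes logical; if FALSE the per-frame volumes are not kept
#'   (use \code{\link{makeSessionDRR}} to stream frames straight to DRRs).
#' @return a list with elements \code{volumes} (list of
#'   AttenuationVolume, or NULL), \code{trajectory} (L x 3 matrix, mm),
#'   \code{trace} (the BreathingTrace) and \code{spec}.
#' @export
makeSession <- function(anatomy, spec, duration_s, fps = 5, volumes = TRUE) {
  trace <- breathingTrace(spec, duration_s, fps)
  A <- trace@displacements
  offset <- spec@baselineShift + spec@setupError
  Pref <- centerOfMass(anatomy@mask, anatomy@spacing)
  trajectory <- sweep(A, 2, Pref + offset, "+")
  colnames(trajectory) <- c("si", "ap", "lr")
  vols <- NULL
  if (volumes) {
    vols <- lapply(seq_len(nrow(A)), function(i)
      applyMotion(anatomy, offset + A[i, ]))
  }
  list(volumes = vols, trajectory = trajectory, trace = trace, spec = spec)
}

#' Simulate a session and stream frames straight to DRRs
#'
#' Memory-light variant of \code{\link{makeSession}}: each moving-tumor
#' volume is projected to a coronal DRR immediately and discarded.
#'
#' @inheritParams makeSession
#' @param I0 incident beam intensity for the Beer-Lambert projection.
#' @return a list with \code{drr} (a raw \linkS4class{DRRSequence}),
#'   \code{trajectory}, \code{trace} and \code{spec}.
#' @export
makeSessionDRR <- function(anatomy, spec, duration_s, fps = 5, I0 = 1) {
  ses <- makeSession(anatomy, spec, duration_s, fps, volumes = FALSE)
  A <- ses$trace@displacements
  offset <- spec@baselineShift + spec@setupError
  d <- dim(anatomy@background)
  stack <- array(0, c(d[1], d[3], nrow(A)))
  for (i in seq_len(nrow(A))) {
    vol <- applyMotion(anatomy, offset + A[i, ])
    stack[, , i] <- projectBeerLambert(vol, I0)@pixels
  }
  drr <- new("DRRSequence", frames = stack,
             spacing = anatomy@spacing[c(1, 3)], fps = fps,
             normalized = FALSE,
             sessionId = paste0(spec@role, "-", spec@seed))
  list(drr = drr, trajectory = ses$trajectory, trace = ses$trace, spec = spec)
}
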