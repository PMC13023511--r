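# Coronal DRR formation with the Beer-Lambert absorption-only model, and
# the image preprocessing chain feeding the forecasting network:
# sequence-level intensity normalization, field-of-view-preserving
# resampling, and ViT patch tokenization.

#' Project a volume to a coronal DRR (Beer-Lambert)
#'
#' Parallel-ray projection along the anterior-posterior axis with the
#' absorption-only Beer-Lambert model:
#' \code{I(z, x) = I0 * exp(-sum_y mu(z, y, x) * dy)}, where dy is the
#' voxel spacing along AP in mm. The result is a coronal view with rows
#' running superior-inferior and columns left-right.
#'
#' @param volume an \linkS4class{AttenuationVolume}.
#' @param I0 incident intensity (> 0), default 1.
#' @return a raw (un-normalized) \linkS4class{DRRImage}.
#' @export
projectBeerLambert <- function(volume, I0 = 1) {
  if (I0 <= 0) stop("I0 must be positive")
  v <- voxels(volume)
  if (min(v) < -1e-12) stop("attenuation values must be non-negative")
  dy <- volume@spacing[2]
  # path integral: sum over axis 2 (AP) -> matrix (SI, LR)
  path <- colSums(aperm(v, c(2, 1, 3)), dims = 1) * dy
  new("DRRImage", pixels = I0 * exp(-path),
      spacing = volume@spacing[c(1, 3)])
}

#' Min-max normalize DRR intensities to [0, 1]
#'
#' For a \linkS4class{DRRSequence} the statistics are computed globally
#' over all frames of the sequence (the default), so breathing-induced
#' intensity modulation survives as a temporal signal; per-frame
#' statistics are available with \code{stats = "frame"}. A constant input
#' maps to all zeros.
#'
#' @param x a \linkS4class{DRRSequence} or \linkS4class{DRRImage}.
#' @param stats "sequence" (global min/max) or "frame" (per-frame min/max);
#'   ignored for a single image.
#' @return the same class with intensities in [0, 1].
#' @export
normalizeImages <- function(x, stats = c("sequence", "frame")) {
  stats <- match.arg(stats)
  rescale <- function(m) {
    r <- range(m)
    if (r[2] - r[1] < .Machine$double.eps) array(0, dim(m))
    else (m - r[1]) / (r[2] - r[1])
  }
  if (is(x, "DRRImage")) {
    x@pixels <- rescale(x@pixels)
    return(x)
  }
  stopifnot(is(x, "DRRSequence"))
  if (stats == "sequence") {
    x@frames <- rescale(x@frames)
  } else {
    for (i in seq_len(dim(x@frames)[3]))
      x@frames[, , i] <- rescale(x@frames[, , i])
  }
  x@normalized <- TRUE
  x
}

# Bilinear sampling positions mapping output pixel centres onto input
# pixel indices while preserving the physical extent (pixel-area model).
.resample_axis <- function(nIn, nOut) {
  # output centre j (0-based) sits at physical fraction (j + 0.5)/nOut of
  # the extent; the matching continuous input index is that position minus
  # the half-pixel offset, clamped to the valid range.
  pos <- ((seq_len(nOut) - 0.5) * nIn / nOut) - 0.5
  pmin(pmax(pos, 0), nIn - 1)
}

.bilinear_matrix <- function(nIn, nOut) {
  # sparse-in-spirit interpolation operator as a dense nOut x nIn matrix
  pos <- .resample_axis(nIn, nOut)
  lo <- floor(pos)
  w <- pos - lo
  M <- matrix(0, nOut, nIn)
  for (j in seq_len(nOut)) {
    i <- lo[j] + 1
    if (w[j] == 0 || i >= nIn) M[j, min(i, nIn)] <- 1
    else { M[j, i] <- 1 - w[j]; M[j, i + 1] <- w[j] }
  }
  M
}

#' Resample a DRR to a target size, preserving the field of view
#'
#' Separable bilinear interpolation to \code{H x W} pixels. The pixel
#' spacing is updated so the physical extent of the image is unchanged
#' (e.g. 512 x 512 at 1 mm becomes 64 x 64 at 8 mm).
#'
#' @param x a \linkS4class{DRRImage} or \linkS4class{DRRSequence}.
#' @param W,H target width and height in pixels (> 0).
#' @return the resampled object with updated spacing.
#' @export
resampleImage <- function(x, W, H) {
  if (W <= 0 || H <= 0) stop("target size must be positive")
  if (is(x, "DRRImage")) {
    hIn <- nrow(x@pixels); wIn <- ncol(x@pixels)
    Mr <- .bilinear_matrix(hIn, H); Mc <- .bilinear_matrix(wIn, W)
    x@pixels <- Mr %*% x@pixels %*% t(Mc)
    x@spacing <- x@spacing * c(hIn / H, wIn / W)
    return(x)
  }
  stopifnot(is(x, "DRRSequence"))
  d <- dim(x@frames)
  Mr <- .bilinear_matrix(d[1], H); Mc <- .bilinear_matrix(d[2], W)
  out <- array(0, c(H, W, d[3]))
  for (i in seq_len(d[3])) out[, , i] <- Mr %*% x@frames[, , i] %*% t(Mc)
  x@frames <- out
  x@spacing <- x@spacing * c(d[1] / H, d[2] / W)
  x
}

#' Number of ViT tokens per frame
#'
#' \code{Ntok = W * H / P^2} for an image of W x H pixels split into
#' non-overlapping P x P patches. Non-divisible patch sizes are rejected
#' rather than padded.
#'
#' @param W,H image width and height in pixels.
#' @param P patch size in pixels; must divide both W and H.
#' @return integer token count.
#' @examples
#' tokenCount(512, 512, 16)  # 1024
#' tokenCount(64, 64, 32)    # 4
#' @export
tokenCount <- function(W, H, P) {
  if (P <= 0 || W %% P != 0 || H %% P != 0)
    stop("patch size must divide both image dimensions")
  as.integer(W * H / P^2)
}

#' Split a frame stack into ordered ViT patch tokens
#'
#' Tokens are ordered (time, patch-row, patch-column); within a token the
#' P x P pixels are flattened row-major. \code{unpatchify} is the exact
#' inverse.
#'
#' @param x a \linkS4class{DRRSequence} or a (H, W, nframes) array.
#' @param P patch size in pixels.
#' @return a (nframes * Ntok) x P^2 numeric matrix of tokens.
#' @export
patchify <- function(x, P) {
  a <- if (is(x, "DRRSequence")) x@frames else x
  d <- dim(a)
  ntok <- tokenCount(d[2], d[1], P)
  npr <- d[1] %/% P; npc <- d[2] %/% P
  out <- matrix(0, d[3] * ntok, P * P)
  for (f in seq_len(d[3])) {
    fr <- a[, , f]
    for (pr in seq_len(npr)) for (pc in seq_len(npc)) {
      patch <- fr[((pr - 1) * P + 1):(pr * P), ((pc - 1) * P + 1):(pc * P)]
      row <- (f - 1) * ntok + (pr - 1) * npc + pc
      out[row, ] <- as.vector(t(patch))  # row-major pixel order
    }
  }
  out
}

#' @rdname patchify
#' @param tokens a token matrix produced by \code{patchify}.
#' @param H,W frame size in pixels.
#' @param nframes number of frames encoded in the token matrix.
#' @return \code{unpatchify}: the reconstructed (H, W, nframes) array.
#' @export
unpatchify <- function(tokens, H, W, nframes) {
  P <- as.integer(sqrt(ncol(tokens)))
  stopifnot(P * P == ncol(tokens))
  ntok <- tokenCount(W, H, P)
  stopifnot(nrow(tokens) == nframes * ntok)
  npr <- H %/% P; npc <- W %/% P
  out <- array(0, c(H, W, nframes))
  for (f in seq_len(nframes)) {
    for (pr in seq_len(npr)) for (pc in seq_len(npc)) {
      row <- (f - 1) * ntok + (pr - 1) * npc + pc
      out[((pr - 1) * P + 1):(pr * P), ((pc - 1) * P + 1):(pc * P), f] <-
        matrix(tokens[row, ], P, P, byrow = TRUE)
    }
  }
  out
}
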