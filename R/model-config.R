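# Model configuration shared by the three architectures.

#' Create a model configuration
#'
#' Defaults follow the study configuration: 64 x 64 DRR inputs with
#' 32-pixel patches (4 tokens per frame), sequences of 8 past frames,
#' horizon T = 5 (one second at 5 fps), and a 6 + 6 layer transformer
#' with embedding dimension 512, 8 attention heads and a 2048-unit
#' feed-forward inner layer. For the ConvLSTM baseline only the
#' \code{convChannels} / \code{convKernel} fields and the shared
#' input/horizon fields are used.
#'
#' @param imageSize integer(2), input frame size (H, W) in pixels.
#' @param patchSize ViT patch size in pixels; must divide H and W.
#' @param nPastFrames number of past frames N per sample.
#' @param horizon forecast horizon T; the decoder emits T + 1 positions
#'   covering offsets 0..T (offset 0 = instantaneous tracking).
#' @param dModel embedding dimension (divisible by \code{nHeads}).
#' @param nHeads number of attention heads.
#' @param dFfn feed-forward inner dimension.
#' @param nEncLayers,nDecLayers encoder / decoder depth.
#' @param dropout dropout rate applied to sub-layer outputs and
#'   embeddings during training.
#' @param convChannels integer vector, hidden channels per ConvLSTM layer.
#' @param convKernel odd ConvLSTM kernel size.
#' @return a validated configuration list.
#' @examples
#' cfg <- modelConfig()                      # full-size study configuration
#' small <- modelConfig(imageSize = c(32, 32), patchSize = 16, dModel = 64,
#'                      nHeads = 4, dFfn = 128, nEncLayers = 2, nDecLayers = 2)
#' @export
modelConfig <- function(imageSize = c(64, 64), patchSize = 32,
                        nPastFrames = 8, horizon = 5,
                        dModel = 512, nHeads = 8, dFfn = 2048,
                        nEncLayers = 6, nDecLayers = 6, dropout = 0.1,
                        convChannels = c(16, 16), convKernel = 3) {
  if (length(imageSize) == 1) imageSize <- rep(imageSize, 2)
  if (dModel %% nHeads != 0) stop("dModel must be divisible by nHeads")
  if (dModel %% 4 != 0)
    stop("dModel must be divisible by 4 (factorized sinusoidal encodings)")
  tokenCount(imageSize[2], imageSize[1], patchSize)  # validates divisibility
  if (nPastFrames < 1) stop("nPastFrames must be >= 1")
  if (horizon < 0) stop("horizon must be >= 0")
  if (convKernel %% 2 != 1) stop("convKernel must be odd")
  list(imageSize = as.integer(imageSize), patchSize = as.integer(patchSize),
       nPastFrames = as.integer(nPastFrames), horizon = as.integer(horizon),
       dModel = as.integer(dModel), nHeads = as.integer(nHeads),
       dFfn = as.integer(dFfn), nEncLayers = as.integer(nEncLayers),
       nDecLayers = as.integer(nDecLayers), dropout = dropout,
       convChannels = as.integer(convChannels),
       convKernel = as.integer(convKernel))
}

.cfg_ntok <- function(cfg) {
  tokenCount(cfg$imageSize[2], cfg$imageSize[1], cfg$patchSize)
}
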