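# Accessor generics and show methods for the core containers.

#' @rdname AttenuationVolume-class
#' @param object an object.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @describeIn AttenuationVolume-class composed attenuation array
#'   (background + tumor component), mm^-1.
#' @export
setMethod("voxels", "AttenuationVolume",
          function(object) object@background + object@tumorDelta)

#' @rdname AttenuationVolume-class
#' @export
setGeneric("tumorMask", function(object) standardGeneric("tumorMask"))

#' @describeIn AttenuationVolume-class binary tumor mask (logical array).
#' @export
setMethod("tumorMask", "AttenuationVolume", function(object) object@mask)

#' @rdname AttenuationVolume-class
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @describeIn AttenuationVolume-class voxel spacing in mm.
#' @export
setMethod("voxelSpacing", "AttenuationVolume", function(object) object@spacing)

#' @describeIn AttenuationVolume-class grid dimensions.
#' @param x an AttenuationVolume.
#' @export
setMethod("dim", "AttenuationVolume", function(x) dim(x@background))

setMethod("show", "AttenuationVolume", function(object) {
  d <- dim(object)
  cat("AttenuationVolume:", paste(d, collapse = " x "), "voxels @",
      paste(object@spacing, collapse = " x "), "mm\n")
  cat("  attenuation range:",
      paste(signif(range(voxels(object)), 4), collapse = " .. "), "mm^-1\n")
  cat("  tumor mask:", sum(object@mask), "voxels, centre of mass",
      paste(round(centerOfMass(object@mask, object@spacing), 2), collapse = ", "),
      "mm\n")
})

#' @rdname BreathingTrace-class
#' @param object an object.
#' @export
setGeneric("displacements", function(object) standardGeneric("displacements"))

#' @describeIn BreathingTrace-class L x 3 displacement matrix in mm.
#' @export
setMethod("displacements", "BreathingTrace", function(object) object@displacements)

#' @describeIn BreathingTrace-class number of samples in the trace.
#' @param x a BreathingTrace.
#' @export
setMethod("length", "BreathingTrace", function(x) nrow(x@displacements))

setMethod("show", "BreathingTrace", function(object) {
  cat("BreathingTrace:", nrow(object@displacements), "samples @",
      object@fps, "fps, period", object@period, "s\n")
  cat("  peak-to-peak amplitude (SI, AP, LR):",
      paste(round(object@amplitude, 2), collapse = ", "), "mm\n")
})

setMethod("show", "SessionSpec", function(object) {
  cat("SessionSpec (", object@role, "), seed ", object@seed, "\n", sep = "")
  cat("  amplitude:", paste(round(object@amplitude, 2), collapse = ", "),
      "mm; period:", object@period, "s\n")
  cat("  baseline shift:", paste(round(object@baselineShift, 2), collapse = ", "),
      "mm; setup error:", paste(round(object@setupError, 2), collapse = ", "),
      "mm; noise sd:", object@noiseSd, "mm\n")
})

#' @rdname DRRImage-class
#' @param object an object.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @describeIn DRRImage-class pixel matrix.
#' @export
setMethod("pixels", "DRRImage", function(object) object@pixels)

#' @describeIn DRRImage-class image dimensions (rows, columns).
#' @param x a DRRImage.
#' @export
setMethod("dim", "DRRImage", function(x) dim(x@pixels))

setMethod("show", "DRRImage", function(object) {
  cat("DRRImage:", nrow(object@pixels), "x", ncol(object@pixels), "pixels @",
      paste(object@spacing, collapse = " x "), "mm, intensity",
      paste(signif(range(object@pixels), 4), collapse = " .. "), "\n")
})

#' @rdname DRRSequence-class
#' @param object an object.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @describeIn DRRSequence-class (H, W, nframes) array of frames.
#' @export
setMethod("frames", "DRRSequence", function(object) object@frames)

#' @describeIn DRRSequence-class number of frames.
#' @param x a DRRSequence.
#' @export
setMethod("length", "DRRSequence", function(x) dim(x@frames)[3])

setMethod("show", "DRRSequence", function(object) {
  d <- dim(object@frames)
  cat("DRRSequence:", d[3], "frames of", d[1], "x", d[2], "pixels @",
      paste(object@spacing, collapse = " x "), "mm,", object@fps, "fps",
      if (object@normalized) "(normalized)" else "(raw)", "\n")
})

setMethod("show", "NormalizationBounds", function(object) {
  cat("NormalizationBounds (margin", object@margin, "mm)\n")
  cat("  Pref:", paste(round(object@Pref, 2), collapse = ", "), "mm\n")
  cat("  Aplan:", paste(round(object@Aplan, 2), collapse = ", "), "mm\n")
  cat("  range:", paste(round(object@Xmin, 2), collapse = ", "), " -> ",
      paste(round(object@Xmax, 2), collapse = ", "), "mm\n")
})

#' @describeIn ForecastSampleSet-class number of supervised windows.
#' @param x a ForecastSampleSet.
#' @export
setMethod("length", "ForecastSampleSet", function(x) length(x@starts))

setMethod("show", "ForecastSampleSet", function(object) {
  d <- dim(object@frames)
  cat("ForecastSampleSet:", length(object@starts), "windows (N =",
      object@nPast, ", T =", object@horizon, ") over", d[3],
      "frames of", d[1], "x", d[2], "px, session", object@sessionId, "\n")
})

setMethod("show", "ForecastModel", function(object) {
  cfg <- object@config
  cat("ForecastModel <", object@arch, ">\n", sep = "")
  cat("  input:", cfg$nPastFrames, "frames of",
      paste(cfg$imageSize, collapse = "x"), "px; horizon T =", cfg$horizon, "\n")
  if (object@arch %in% c("trajvivit", "vit"))
    cat("  patch", cfg$patchSize, "-> ",
        tokenCount(cfg$imageSize[2], cfg$imageSize[1], cfg$patchSize),
        "tokens/frame; d_model", cfg$dModel, ",", cfg$nHeads, "heads, FFN",
        cfg$dFfn, ",", cfg$nEncLayers, "+", cfg$nDecLayers, "layers\n")
  else
    cat("  ConvLSTM channels:", paste(cfg$convChannels, collapse = ", "),
        "kernel", cfg$convKernel, "\n")
  cat("  parameters:", nParams(object),
      if (.has_lora(object@params)) "(LoRA adapters attached)" else "", "\n")
  if (length(object@tags))
    cat("  tags:", paste(names(object@tags), unlist(lapply(object@tags, format)),
                         sep = "=", collapse = ", "), "\n")
})

#' Total parameter count of a model
#'
#' @param model a \linkS4class{ForecastModel}.
#' @return integer, the number of scalar weights (including any LoRA
#'   adapters).
#' @export
nParams <- function(model) {
  stopifnot(is(model, "ForecastModel"))
  sum(vapply(.flatten_params(model@params), length, integer(1)))
}
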