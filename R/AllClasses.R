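#' @import methods
NULL

#' AttenuationVolume: a 3D attenuation grid with a tumor mask
#'
#' Container for a thorax-like volume of linear attenuation coefficients
#' (mm^-1) together with a binary tumor mask. The volume is stored
#' decomposed into a static background and an additive tumor component so
#' that rigid tumor motion can be simulated by resampling the tumor
#' component alone, leaving the surrounding anatomy untouched.
#'
#' Axis convention: array axis 1 is superior-inferior (SI, "z"), axis 2 is
#' anterior-posterior (AP, "y"), axis 3 is left-right (LR, "x"). World
#' coordinates are \code{(index - 1) * spacing} in mm (0-based voxel
#' indexing at voxel centres).
#'
#' @slot background 3D array, attenuation without the tumor (mm^-1).
#' @slot tumorDelta 3D array, additive tumor attenuation (mm^-1); the
#'   composed volume is \code{background + tumorDelta}.
#' @slot mask 3D logical array, the binary tumor mask.
#' @slot spacing numeric(3), per-axis voxel size in mm.
#' @exportClass AttenuationVolume
setClass("AttenuationVolume",
  representation(background = "array", tumorDelta = "array",
                 mask = "array", spacing = "numeric"))

setValidity("AttenuationVolume", function(object) {
  msg <- character()
  d <- dim(object@background)
  if (length(d) != 3L) msg <- c(msg, "background must be a 3D array")
  if (!identical(dim(object@tumorDelta), d))
    msg <- c(msg, "tumorDelta dimensions differ from background")
  if (!identical(dim(object@mask), d))
    msg <- c(msg, "mask dimensions differ from background")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (min(object@background + object@tumorDelta) < -1e-12)
    msg <- c(msg, "composed attenuation must be non-negative")
  if (!any(object@mask)) msg <- c(msg, "tumor mask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' BreathingTrace: a sampled 3-axis respiratory displacement signal
#'
#' @slot displacements L x 3 matrix of displacements A(t) in mm
#'   (columns SI, AP, LR).
#' @slot fps sampling rate in frames per second.
#' @slot period nominal respiratory period in seconds.
#' @slot amplitude numeric(3), per-axis peak-to-peak displacement in mm.
#' @exportClass BreathingTrace
setClass("BreathingTrace",
  representation(displacements = "matrix", fps = "numeric",
                 period = "numeric", amplitude = "numeric"))

setValidity("BreathingTrace", function(object) {
  msg <- character()
  if (nrow(object@displacements) < 1L) msg <- c(msg, "trace must have length >= 1")
  if (ncol(object@displacements) != 3L) msg <- c(msg, "trace must have 3 columns")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (object@period <= 0) msg <- c(msg, "period must be positive")
  if (length(msg)) msg else TRUE
})

#' SessionSpec: parameters of a planning or treatment imaging session
#'
#' Describes one simulated free-breathing session. Treatment sessions may
#' differ from the planning session by amplitude, period, a residual
#' baseline shift (bounded by 5 mm per axis, the margin the normalization
#' bounds are built to absorb), a rigid setup error, and per-frame noise.
#'
#' @slot role "planning" or "treatment".
#' @slot amplitude numeric(3), per-axis peak-to-peak breathing amplitude (mm).
#' @slot period respiratory period in seconds.
#' @slot baselineShift numeric(3), residual inter-session shift in mm
#'   (|shift| <= 5 mm per axis).
#' @slot setupError numeric(3), rigid patient-positioning error in mm.
#' @slot noiseSd per-frame Gaussian displacement noise sd in mm.
#' @slot seed integer seed controlling the session's randomness.
#' @exportClass SessionSpec
setClass("SessionSpec",
  representation(role = "character", amplitude = "numeric", period = "numeric",
                 baselineShift = "numeric", setupError = "numeric",
                 noiseSd = "numeric", seed = "numeric"))

setValidity("SessionSpec", function(object) {
  msg <- character()
  if (!object@role %in% c("planning", "treatment"))
    msg <- c(msg, "role must be 'planning' or 'treatment'")
  if (length(object@amplitude) != 3L || any(object@amplitude < 0))
    msg <- c(msg, "amplitude must be 3 non-negative values (mm)")
  if (object@period <= 0) msg <- c(msg, "period must be positive")
  if (length(object@baselineShift) != 3L || any(abs(object@baselineShift) > 5 + 1e-12))
    msg <- c(msg, "baselineShift must be within +/- 5 mm per axis")
  if (length(object@setupError) != 3L)
    msg <- c(msg, "setupError must have 3 components")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DRRImage: a single digitally reconstructed radiograph
#'
#' @slot pixels numeric matrix; rows run superior-inferior, columns
#'   left-right (a coronal view).
#' @slot spacing numeric(2), pixel size in mm (row, column).
#' @exportClass DRRImage
setClass("DRRImage",
  representation(pixels = "matrix", spacing = "numeric"))

setValidity("DRRImage", function(object) {
  msg <- character()
  if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
    msg <- c(msg, "pixels must be a non-empty matrix")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 2 positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' DRRSequence: an ordered stack of DRR frames
#'
#' @slot frames 3D array (H, W, nframes).
#' @slot spacing numeric(2), pixel size in mm (row, column).
#' @slot fps frame rate in frames per second.
#' @slot normalized logical, TRUE once intensities are min-max scaled to [0,1].
#' @slot sessionId character tag linking the sequence to its session.
#' @exportClass DRRSequence
setClass("DRRSequence",
  representation(frames = "array", spacing = "numeric", fps = "numeric",
                 normalized = "logical", sessionId = "character"))

setValidity("DRRSequence", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L) msg <- c(msg, "frames must be a 3D array")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 2 positive values (mm)")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (isTRUE(object@normalized)) {
    rng <- range(object@frames)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      msg <- c(msg, "normalized frames must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' NormalizationBounds: per-axis position normalization range
#'
#' The motion range used to map tumor positions to [-1, 1] per axis:
#' \code{Xmax = Pref + (Aplan + margin)}, \code{Xmin = Pref - (Aplan + margin)}.
#' Pref is the reference (planning mean) position and Aplan the per-axis
#' maximum displacement amplitude observed during planning; the margin
#' (default 5 mm) absorbs residual baseline shifts between sessions so
#' treatment positions stay inside the training distribution.
#'
#' @slot Pref numeric(3), reference position in mm.
#' @slot Aplan numeric(3), planning amplitude in mm.
#' @slot margin scalar margin in mm.
#' @slot Xmin,Xmax numeric(3), the derived per-axis bounds in mm.
#' @exportClass NormalizationBounds
setClass("NormalizationBounds",
  representation(Pref = "numeric", Aplan = "numeric", margin = "numeric",
                 Xmin = "numeric", Xmax = "numeric"))

setValidity("NormalizationBounds", function(object) {
  msg <- character()
  if (any(object@Aplan < 0)) msg <- c(msg, "Aplan must be non-negative")
  if (object@margin < 0) msg <- c(msg, "margin must be non-negative")
  if (any(abs(object@Xmax - (object@Pref + object@Aplan + object@margin)) > 1e-9))
    msg <- c(msg, "Xmax must equal Pref + (Aplan + margin)")
  if (any(abs(object@Xmin - (object@Pref - object@Aplan - object@margin)) > 1e-9))
    msg <- c(msg, "Xmin must equal Pref - (Aplan + margin)")
  if (any(object@Xmax <= object@Xmin))
    msg <- c(msg, "Xmax must exceed Xmin on every axis")
  if (length(msg)) msg else TRUE
})

#' ForecastSampleSet: supervised (past frames, future positions) windows
#'
#' Sliding-window pairing of N past DRR frames with the T+1 normalized
#' tumor positions at offsets 0..T from the last observed frame (offset 0
#' is instantaneous tracking). Windows are stored by their start index into
#' the underlying frame stack to avoid duplicating pixel data.
#'
#' @slot frames 3D array (H, W, L), the normalized DRR stack.
#' @slot trajectory L x 3 matrix of true centroid positions in mm.
#' @slot targets nwin x (T+1) x 3 array of normalized target positions.
#' @slot starts integer vector of window start frames (1-based).
#' @slot nPast number of past frames N per sample.
#' @slot horizon forecast horizon T (offsets 0..T are supervised).
#' @slot bounds the NormalizationBounds used for the targets.
#' @slot sessionId character tag of the originating session.
#' @exportClass ForecastSampleSet
setClass("ForecastSampleSet",
  representation(frames = "array", trajectory = "matrix", targets = "array",
                 starts = "integer", nPast = "numeric", horizon = "numeric",
                 bounds = "NormalizationBounds", sessionId = "character"))

setValidity("ForecastSampleSet", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L) msg <- c(msg, "frames must be 3D")
  if (nrow(object@trajectory) != dim(object@frames)[3])
    msg <- c(msg, "trajectory must align 1:1 with frames")
  if (length(dim(object@targets)) != 3L ||
      dim(object@targets)[1] != length(object@starts) ||
      dim(object@targets)[2] != object@horizon + 1 ||
      dim(object@targets)[3] != 3L)
    msg <- c(msg, "targets must be nwin x (T+1) x 3")
  if (object@nPast < 1) msg <- c(msg, "nPast must be >= 1")
  if (object@horizon < 0) msg <- c(msg, "horizon must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ForecastModel: a position-forecasting network
#'
#' Wraps one of the three interchangeable architectures (encoder-decoder
#' vision transformer, encoder-only vision transformer, convolutional
#' LSTM) together with its configuration and parameters. All three expose
#' the same (past frames, horizon) -> (T+1) x 3 forecasting contract.
#'
#' @slot arch one of "trajvivit", "vit", "convlstm".
#' @slot config the model configuration list (see \code{\link{modelConfig}}).
#' @slot params nested named list of weight arrays.
#' @slot tags free-form metadata (training strategy, held-out patient, ...).
#' @exportClass ForecastModel
setClass("ForecastModel",
  representation(arch = "character", config = "list", params = "list",
                 tags = "list"))

setValidity("ForecastModel", function(object) {
  if (!object@arch %in% c("trajvivit", "vit", "convlstm"))
    "arch must be 'trajvivit', 'vit' or 'convlstm'" else TRUE
})
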