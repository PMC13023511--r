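# I/O: NIfTI volumes and DRR stacks, CSV trajectories, YAML session
# sidecars, and model checkpoints with a config-hash integrity check.

#' Write / read an attenuation volume as NIfTI
#'
#' The composed attenuation volume and the binary mask are written as two
#' NIfTI files (\code{<path>.nii.gz} and \code{<path>_mask.nii.gz}) with
#' the voxel spacing in the header.
#'
#' @param volume an \linkS4class{AttenuationVolume}.
#' @param path output path prefix (without extension).
#' @return \code{writeVolume}: the path prefix, invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(voxels(volume))
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  msk <- RNifti::asNifti(array(as.integer(volume@mask), dim(volume@mask)))
  RNifti::pixdim(msk) <- volume@spacing
  RNifti::writeNifti(msk, paste0(path, "_mask.nii.gz"))
  invisible(path)
}

#' @rdname writeVolume
#' @return \code{readVolume}: an \linkS4class{AttenuationVolume}
#'   (tumor/background decomposition is re-derived from the mask).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  msk <- RNifti::readNifti(paste0(path, "_mask.nii.gz"))
  spacing <- RNifti::pixdim(img)[1:3]
  attenuationVolume(array(as.numeric(img), dim(img)[1:3]),
                    array(as.numeric(msk) > 0.5, dim(msk)[1:3]), spacing)
}

#' Write / read a DRR sequence as a NIfTI stack plus YAML sidecar
#'
#' Frames are stacked along the third axis of \code{<path>.nii.gz}; frame
#' rate, pixel spacing, normalization state and session id go to
#' \code{<path>.yaml}.
#'
#' @param drrSeq a \linkS4class{DRRSequence}.
#' @param path output path prefix (without extension).
#' @return \code{writeDRRSequence}: the path prefix, invisibly.
#' @export
writeDRRSequence <- function(drrSeq, path) {
  img <- RNifti::asNifti(drrSeq@frames)
  RNifti::pixdim(img) <- c(drrSeq@spacing, 1 / drrSeq@fps)
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  yaml::write_yaml(list(fps = drrSeq@fps,
                        spacing_mm = as.numeric(drrSeq@spacing),
                        normalized = drrSeq@normalized,
                        sessionId = drrSeq@sessionId),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeDRRSequence
#' @return \code{readDRRSequence}: a \linkS4class{DRRSequence}.
#' @export
readDRRSequence <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  new("DRRSequence", frames = array(as.numeric(img), dim(img)[1:3]),
      spacing = as.numeric(meta$spacing_mm), fps = meta$fps,
      normalized = isTRUE(meta$normalized),
      sessionId = as.character(meta$sessionId))
}

#' Write / read a centroid trajectory as CSV
#'
#' Columns \code{t_s, x_mm, y_mm, z_mm} with the radiological axis names:
#' x = left-right, y = anterior-posterior, z = superior-inferior (the
#' reverse of the internal SI/AP/LR array-axis order).
#'
#' @param trajectory L x 3 matrix (SI, AP, LR) in mm.
#' @param fps frame rate used to derive the time column.
#' @param file output CSV path.
#' @return \code{writeTrajectory}: the file path, invisibly.
#' @export
writeTrajectory <- function(trajectory, fps, file) {
  df <- data.frame(t_s = (seq_len(nrow(trajectory)) - 1) / fps,
                   x_mm = trajectory[, 3], y_mm = trajectory[, 2],
                   z_mm = trajectory[, 1])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrajectory
#' @return \code{readTrajectory}: a list with \code{trajectory}
#'   (L x 3, SI/AP/LR order) and \code{fps}.
#' @export
readTrajectory <- function(file) {
  df <- utils::read.csv(file)
  traj <- cbind(si = df$z_mm, ap = df$y_mm, lr = df$x_mm)
  fps <- if (nrow(df) > 1) 1 / (df$t_s[2] - df$t_s[1]) else NA_real_
  list(trajectory = traj, fps = fps)
}

#' Write / read session metadata as a YAML sidecar
#'
#' @param spec a \linkS4class{SessionSpec}.
#' @param file output YAML path.
#' @return \code{writeSessionSpec}: the file path, invisibly.
#' @export
writeSessionSpec <- function(spec, file) {
  yaml::write_yaml(list(role = spec@role,
                        amplitude_mm = as.numeric(spec@amplitude),
                        period_s = spec@period,
                        baseline_shift_mm = as.numeric(spec@baselineShift),
                        setup_error_mm = as.numeric(spec@setupError),
                        noise_sd_mm = spec@noiseSd, seed = spec@seed),
                   file)
  invisible(file)
}

#' @rdname writeSessionSpec
#' @return \code{readSessionSpec}: a \linkS4class{SessionSpec}.
#' @export
readSessionSpec <- function(file) {
  m <- yaml::read_yaml(file)
  sessionSpec(m$role, amplitude = m$amplitude_mm, period = m$period_s,
              baselineShift = m$baseline_shift_mm,
              setupError = m$setup_error_mm, noiseSd = m$noise_sd_mm,
              seed = m$seed)
}

# 32-bit polynomial rolling hash of the YAML-serialized config; used for
# the checkpoint integrity check (not cryptographic)
.config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Save / load a model checkpoint
#'
#' A single-file checkpoint containing the architecture, the
#' configuration (with its hash) and all weights. On load the stored
#' configuration is re-hashed and must match, guarding against partially
#' edited checkpoints.
#'
#' @param model a \linkS4class{ForecastModel}.
#' @param file checkpoint path.
#' @return \code{saveModel}: the file path, invisibly.
#' @export
saveModel <- function(model, file) {
  saveRDS(list(arch = model@arch, config = model@config,
               configHash = .config_hash(model@config),
               params = model@params, tags = model@tags), file)
  invisible(file)
}

#' @rdname saveModel
#' @param expectedConfig optional configuration the checkpoint must
#'   match exactly (strict hash comparison).
#' @return \code{loadModel}: a \linkS4class{ForecastModel}.
#' @export
loadModel <- function(file, expectedConfig = NULL) {
  ck <- readRDS(file)
  if (!identical(.config_hash(ck$config), ck$configHash))
    stop("checkpoint config hash mismatch; file corrupted or edited")
  if (!is.null(expectedConfig) &&
      !identical(.config_hash(expectedConfig), ck$configHash))
    stop("checkpoint does not match the expected configuration")
  new("ForecastModel", arch = ck$arch, config = ck$config,
      params = ck$params, tags = ck$tags)
}
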