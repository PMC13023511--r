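# Shared fixtures, all generated in code at test time.

# small thorax phantom: 24^3 voxels at 4 mm, 9 mm tumor in the right lung
tinyAnatomy <- function(seed = 1) {
  makeAnatomy(c(24, 24, 24), 4, tumorCenter = c(46, 42, 66),
              tumorRadius = 9, seed = seed)
}

# scaled-down transformer configuration for fast unit tests
tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(imageSize = c(16, 16), patchSize = 8, nPastFrames = 3,
         horizon = 2, dModel = 16, nHeads = 2, dFfn = 24,
         nEncLayers = 1, nDecLayers = 1, dropout = 0,
         convChannels = c(2, 2), convKernel = 3),
    list(...))
  do.call(modelConfig, args)
}

randFrames <- function(H = 16, W = 16, N = 3, seed = 1) {
  withr::with_seed(seed, array(runif(H * W * N), c(H, W, N)))
}

# synthetic sample set with random frames and a smooth sinusoidal
# trajectory; cheap stand-in for trainer/eval plumbing tests
tinySampleSet <- function(L = 20, N = 3, T = 2, H = 16, W = 16, seed = 1,
                          id = "toy") {
  withr::with_seed(seed, {
    fr <- array(runif(H * W * L), c(H, W, L))
    t <- seq_len(L)
    traj <- cbind(50 + 5 * sin(2 * pi * t / 10),
                  40 + 2 * cos(2 * pi * t / 10),
                  60 + 1 * sin(2 * pi * t / 10 + 1))
  })
  seqd <- new("DRRSequence", frames = fr, spacing = c(4, 4), fps = 5,
              normalized = TRUE, sessionId = id)
  bounds <- boundsFromTrajectory(traj)
  makeWindows(seqd, traj, N = N, T = T, bounds)
}
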