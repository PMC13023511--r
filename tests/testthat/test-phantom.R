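test_that("tumor mask matches brute-force sphere enumeration", {
  vol <- makeAnatomy(c(64, 64, 64), 2, tumorCenter = c(64, 56, 90),
                     tumorRadius = 8, seed = 3)
  # independent oracle: loop over all voxel centres
  cnt <- 0L
  for (i in 1:64) for (j in 1:64) for (k in 1:64) {
    w <- (c(i, j, k) - 1) * 2
    if (sum((w - c(64, 56, 90))^2) <= 64) cnt <- cnt + 1L
  }
  expect_identical(sum(tumorMask(vol)), cnt)
})

test_that("anatomy respects invariants and seeded determinism", {
  vol <- tinyAnatomy(seed = 7)
  expect_gte(min(voxels(vol)), 0)
  expect_gt(sum(tumorMask(vol)), 0)
  vol2 <- tinyAnatomy(seed = 7)
  expect_identical(voxels(vol), voxels(vol2))
  vol3 <- tinyAnatomy(seed = 8)
  expect_false(identical(voxels(vol), voxels(vol3)))
  expect_error(makeAnatomy(c(24, 24, 24), 4, c(2, 2, 2), 9), "fit")
  expect_error(makeAnatomy(c(24, 24, 24), 4, c(46, 42, 66), -1), "positive")
})

test_that("breathing trace has the stated amplitude, length and period", {
  spec <- sessionSpec("planning", amplitude = c(10, 3, 2), period = 4,
                      noiseSd = 0)
  tr <- breathingTrace(spec, duration_s = 4, fps = 100)
  A <- displacements(tr)
  ptp <- apply(A, 2, function(x) diff(range(x)))
  expect_equal(ptp, c(si = 10, ap = 3, lr = 2), tolerance = 0.01)
  expect_equal(nrow(displacements(breathingTrace(spec, 20, 5))), 100L)
  # exact periodicity over two cycles when noiseless
  tr2 <- breathingTrace(spec, duration_s = 8, fps = 5)
  A2 <- displacements(tr2)
  expect_equal(A2[1:20, ], A2[21:40, ], tolerance = 1e-12)
  # per-axis maximum bounded by the amplitude
  expect_true(all(apply(abs(A), 2, max) <= spec@amplitude + 1e-9))
  expect_error(breathingTrace(spec, -1, 5), "positive")
})

test_that("centre of mass equals brute-force mean of voxel coordinates", {
  m <- array(FALSE, c(8, 8, 8))
  m[4, 5, 6] <- TRUE
  expect_equal(centerOfMass(m, c(2, 2, 2)), c(6, 8, 10))
  # random mask vs. explicit loop
  withr::with_seed(11, {
    m2 <- array(runif(8^3) < 0.2, c(8, 8, 8))
  })
  acc <- c(0, 0, 0); n <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8) if (m2[i, j, k]) {
    acc <- acc + (c(i, j, k) - 1) * c(1.5, 2, 2.5); n <- n + 1
  }
  expect_equal(centerOfMass(m2, c(1.5, 2, 2.5)), acc / n, tolerance = 1e-9)
  # symmetric sphere: centroid at the sphere centre within half a voxel
  vol <- tinyAnatomy()
  expect_lt(max(abs(centerOfMass(tumorMask(vol), 4) - c(46, 42, 66))), 2)
  expect_error(centerOfMass(array(FALSE, c(2, 2, 2)), 1), "empty")
})

test_that("applyMotion translates the tumor and conserves attenuation", {
  vol <- tinyAnatomy()
  expect_identical(applyMotion(vol, c(0, 0, 0)), vol)
  # 8 mm shift along LR on 4 mm spacing: centroid moves by 8 mm
  sh <- applyMotion(vol, c(0, 0, 8))
  c0 <- centerOfMass(tumorMask(vol), 4)
  c1 <- centerOfMass(tumorMask(sh), 4)
  expect_lt(max(abs(c1 - c0 - c(0, 0, 8))), 2)  # within half a voxel
  # background untouched, total attenuation conserved under interpolation
  expect_identical(sh@background, vol@background)
  sub <- applyMotion(vol, c(3.1, -2.7, 1.9))
  expect_lt(abs(sum(voxels(sub)) - sum(voxels(vol))) / sum(voxels(vol)),
            0.005)
  expect_error(applyMotion(vol, c(0, 0, 200)), "outside")
})

test_that("sub-voxel shift centroid matches brute-force interpolated mass", {
  vol <- tinyAnatomy()
  d <- c(2.3, 0, 0)
  sh <- applyMotion(vol, d)
  # oracle: centroid of the continuously shifted mask field
  msk <- tumorMask(vol) + 0
  svox <- d / 4
  idx <- which(array(TRUE, dim(msk)), arr.ind = TRUE)
  # brute-force trilinear sample of the shifted field at every voxel
  val <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ] - svox
    f <- floor(p); w <- p - f
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      q <- f + c(a, b, cc)
      if (all(q >= 1) && all(q <= dim(msk))) {
        wt <- prod(ifelse(c(a, b, cc) == 1, w, 1 - w))
        acc <- acc + wt * msk[q[1], q[2], q[3]]
      }
    }
    val[r] <- acc
  }
  keep <- val >= 0.5
  oracle <- unname((colSums(idx[keep, , drop = FALSE]) / sum(keep) - 1) * 4)
  expect_equal(centerOfMass(tumorMask(sh), 4), oracle, tolerance = 1e-9)
})

test_that("session construction yields analytic trajectories and counts", {
  vol <- tinyAnatomy()
  spec <- sessionSpec("planning", amplitude = c(6, 2, 1), period = 4,
                      baselineShift = c(2, 0, -1), setupError = c(1, 1, 0),
                      noiseSd = 0)
  ses <- makeSession(vol, spec, duration_s = 4, fps = 5, volumes = FALSE)
  expect_equal(nrow(ses$trajectory), 20L)
  Pref <- centerOfMass(tumorMask(vol), 4)
  expected <- sweep(displacements(ses$trace), 2,
                    Pref + spec@baselineShift + spec@setupError, "+")
  expect_equal(unname(ses$trajectory), unname(expected), tolerance = 1e-12)
  # static case: zero amplitude and shifts give a constant trajectory
  spec0 <- sessionSpec("planning", amplitude = c(0, 0, 0), period = 4)
  ses0 <- makeSession(vol, spec0, 2, 5, volumes = FALSE)
  expect_equal(apply(ses0$trajectory, 2, stats::sd), c(si = 0, ap = 0, lr = 0))
  expect_equal(unname(ses0$trajectory[1, ]), unname(Pref))
})

test_that("treatment trajectories stay inside planning bounds (5 mm margin)", {
  vol <- tinyAnatomy()
  plan <- sessionSpec("planning", amplitude = c(8, 3, 2), period = 4, seed = 2)
  pses <- makeSession(vol, plan, 20, 5, volumes = FALSE)
  bounds <- boundsFromTrajectory(pses$trajectory)
  for (s in 1:3) {
    treat <- sessionSpec("treatment", amplitude = c(8, 3, 2) * 0.95,
                         period = 3.8, baselineShift = c(4, -3, 2),
                         noiseSd = 0, seed = s)
    tses <- makeSession(vol, treat, 12, 5, volumes = FALSE)
    expect_true(all(sweep(tses$trajectory, 2, bounds@Xmax) <= 1e-9))
    expect_true(all(sweep(tses$trajectory, 2, bounds@Xmin) >= -1e-9))
  }
})

test_that("session specs validate the 5 mm baseline-shift bound", {
  expect_error(sessionSpec("treatment", baselineShift = c(6, 0, 0)), "5 mm")
  expect_s4_class(sessionSpec("treatment", baselineShift = c(5, -5, 5)),
                  "SessionSpec")
})
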