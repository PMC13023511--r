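test_that("learning-rate schedule hits the specified boundary values", {
  cfg <- trainConfig(epochs = 10, batchSize = 4, peakLr = 2e-3)
  total <- 200  # 20 steps per epoch
  expect_equal(lrAt(0, total, cfg), cfg$peakLr / 100)
  expect_equal(lrAt(19, total, cfg), cfg$peakLr)       # last warmup step
  expect_equal(lrAt(199, total, cfg), cfg$peakLr / 100)
  lrs <- sapply(0:199, lrAt, totalSteps = total, cfg = cfg)
  # monotone up through warmup, monotone down after, continuous joint
  expect_true(all(diff(lrs[1:20]) > 0))
  expect_true(all(diff(lrs[20:200]) < 0))
  expect_lt(abs(lrs[21] - lrs[20]), cfg$peakLr * 0.01)
  expect_error(lrAt(-1, total, cfg), "step")
  expect_error(lrAt(200, total, cfg), "step")
})

test_that("RMSE loss matches its definition and a loop oracle", {
  p <- matrix(1:6 / 10, 2, 3)
  expect_equal(rmseLoss(p, p), 0)
  expect_equal(rmseLoss(p + 0.3, p), 0.3)
  withr::with_seed(21, {
    a <- array(rnorm(24), c(4, 3, 2)); b <- array(rnorm(24), c(4, 3, 2))
  })
  acc <- 0
  for (i in 1:4) for (j in 1:3) for (k in 1:2) acc <- acc + (a[i,j,k] - b[i,j,k])^2
  expect_equal(rmseLoss(a, b), sqrt(acc / 24), tolerance = 1e-12)
  expect_error(rmseLoss(matrix(0, 2, 3), matrix(0, 3, 2)), "shape")
})

test_that("training is seed-deterministic, wires the schedule, and learns", {
  set <- tinySampleSet(L = 30, N = 3, T = 2, seed = 3)
  cfg <- tinyConfig()
  m <- buildTrajViViT(cfg, seed = 1)
  tc <- trainConfig(epochs = 4, batchSize = 8, peakLr = 3e-3, seed = 7)
  fit1 <- trainModel(m, set, tc)
  fit2 <- trainModel(m, set, tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model@params, fit2$model@params)
  # recorded learning rates match lrAt exactly
  total <- nrow(fit1$stepLog)
  expect_equal(fit1$stepLog$lr,
               sapply(fit1$stepLog$step, lrAt, totalSteps = total, cfg = tc))
  # loss decreases on this easy smooth-trajectory task
  expect_lt(fit1$history$loss[4], fit1$history$loss[1])
  expect_error(trainModel(m, list(), tc), "empty|set")
})

test_that("one-shot baselines train under the same loop", {
  set <- tinySampleSet(L = 20, N = 3, T = 2, seed = 4)
  tc <- trainConfig(epochs = 2, batchSize = 8, peakLr = 3e-3, seed = 1)
  for (build in list(buildEncoderViT, buildConvLSTM)) {
    fit <- trainModel(build(tinyConfig(), seed = 2), set, tc)
    expect_identical(nrow(fit$history), 2L)
    expect_true(all(is.finite(fit$history$loss)))
  }
})

test_that("multi-patient pooling excludes the held-out patient", {
  sets <- list(p1 = tinySampleSet(L = 12, seed = 1, id = "p1"),
               p2 = tinySampleSet(L = 12, seed = 2, id = "p2"),
               p3 = tinySampleSet(L = 12, seed = 3, id = "p3"))
  m <- buildTrajViViT(tinyConfig(), seed = 1)
  tc <- trainConfig(epochs = 1, batchSize = 8, peakLr = 1e-3, seed = 1)
  fit <- trainMultiPatient(sets, "p2", m, tc)
  expect_identical(fit$model@tags$heldOut, "p2")
  expect_identical(fit$model@tags$strategy, "MP")
  pool <- sets[setdiff(names(sets), "p2")]
  expect_identical(unname(sort(vapply(pool, function(s) s@sessionId, ""))),
                   c("p1", "p3"))
  expect_error(trainMultiPatient(sets, "p9", m, tc), "not found")
  expect_error(trainMultiPatient(sets["p1"], "p1", m, tc), "2 patients")
  # determinism of the pooled run
  fit2 <- trainMultiPatient(sets, "p2", m, tc)
  expect_identical(fit$model@params, fit2$model@params)
})

test_that("LoRA adapters start at exact identity and count parameters", {
  cfg <- tinyConfig()
  base <- buildTrajViViT(cfg, seed = 6)
  lcfg <- loraConfig(rank = 2, seed = 3)
  adapted <- addLoraAdapters(base, lcfg)
  fr <- randFrames(16, 16, 3, seed = 8)
  withr::with_seed(9, {
    tg <- matrix(runif(9, -1, 1), 3, 3)
  })
  expect_identical(forwardTeacherForced(adapted, fr, tg),
                   forwardTeacherForced(base, fr, tg))
  expect_identical(forecastAutoregressive(adapted, fr, 2),
                   forecastAutoregressive(base, fr, 2))
  # trainable adapter parameters: r * (d_in + d_out) per adapted matrix,
  # two matrices (Q, V) per attention block
  d <- cfg$dModel
  nAttn <- cfg$nEncLayers + 2 * cfg$nDecLayers
  expected <- nAttn * 2 * lcfg$rank * (d + d)
  trainable <- grep("\\.lora\\.(qA|qB|vA|vB)$",
                    names(drrtrack:::.flatten_params(adapted@params)),
                    value = TRUE)
  got <- sum(vapply(drrtrack:::.flatten_params(adapted@params)[trainable],
                    length, integer(1)))
  expect_identical(got, as.integer(expected))
  # merging the (still zero) adapters reproduces the base weights
  merged <- mergeLora(adapted)
  expect_equal(merged@params$enc$layer1$attn$Wq, base@params$enc$layer1$attn$Wq)
})

test_that("fine-tuning updates only the adapters and moves the output", {
  set <- tinySampleSet(L = 12, N = 3, T = 2, seed = 5)
  base <- buildTrajViViT(tinyConfig(), seed = 2)
  res <- finetuneLoRA(base, set, loraConfig(rank = 2, epochs = 3, seed = 4))
  ft <- res$model
  expect_identical(ft@tags$strategy, "FT")
  # base weights untouched
  expect_identical(ft@params$enc$layer1$attn$Wq,
                   base@params$enc$layer1$attn$Wq)
  expect_identical(ft@params$head, base@params$head)
  # adapters moved away from zero
  expect_gt(max(abs(ft@params$enc$layer1$attn$lora$qB)), 0)
  expect_error(finetuneLoRA(base, subsetWindows(set, integer(0)),
                            loraConfig()), "shot")
})
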