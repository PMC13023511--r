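test_that("positional encodings are bounded, injective and sinusoidal", {
  pe <- positionalEncoding(4, 4, 16)
  expect_identical(dim(pe), c(16L, 16L))
  expect_true(all(pe >= -2 & pe <= 2))
  # distinct (frame, patch) pairs get distinct vectors (exhaustive 4x4)
  expect_identical(nrow(unique(round(pe, 12))), 16L)
  # temporal component at frame 0 is the standard position-0 sinusoid
  s0 <- sinusoidalEncoding(1, 8)
  expect_equal(s0[1, seq(1, 8, 2)], rep(0, 4))   # sin(0)
  expect_equal(s0[1, seq(2, 8, 2)], rep(1, 4))   # cos(0)
  # temporal channels vary with the frame index, spatial channels with
  # the patch index, and the two factors occupy disjoint halves
  pe31 <- positionalEncoding(3, 1, 16)
  expect_equal(pe31[, 1:8], sinusoidalEncoding(3, 8))
  expect_equal(pe31[1, 9:16], sinusoidalEncoding(1, 8)[1, ])
  pe13 <- positionalEncoding(1, 3, 16)
  expect_equal(pe13[, 9:16], sinusoidalEncoding(3, 8))
})

test_that("builds are seed-deterministic with the declared shapes", {
  cfg <- tinyConfig()
  m1 <- buildTrajViViT(cfg, seed = 5)
  m2 <- buildTrajViViT(cfg, seed = 5)
  expect_identical(m1@params, m2@params)
  expect_false(identical(m1@params, buildTrajViViT(cfg, seed = 6)@params))
  # encoder memory has N x Ntok tokens
  fr <- randFrames(16, 16, 3)
  mem <- drrtrack:::.tv_encode(m1, fr)$mem
  expect_identical(nrow(mem), 3L * tokenCount(16, 16, 8))
  expect_identical(ncol(mem), cfg$dModel)
  # encoder-only ViT adds one CLS token and emits (T+1) x 3 one-shot
  vit <- buildEncoderViT(cfg, seed = 5)
  fv <- drrtrack:::.vit_forward(vit, fr)
  expect_identical(nrow(fv$cache$fin$y), 3L * tokenCount(16, 16, 8) + 1L)
  expect_identical(dim(fv$preds), c(3L, 3L))
  cl <- buildConvLSTM(cfg, seed = 5)
  expect_identical(dim(forecastAutoregressive(cl, fr)), c(3L, 3L))
  expect_identical(buildConvLSTM(cfg, seed = 5)@params, cl@params)
})

test_that("parameter count equals the closed-form shape arithmetic", {
  cfg <- tinyConfig()
  d <- cfg$dModel; f <- cfg$dFfn; P <- cfg$patchSize
  attn <- 4 * (d * d + d)
  ffn <- d * f + f + f * d + d
  encL <- attn + ffn + 4 * d           # two layer norms
  decL <- 2 * attn + ffn + 6 * d       # self + cross, three layer norms
  expected <- (P * P * d + d) +                       # patch embedding
    cfg$nEncLayers * encL + cfg$nDecLayers * decL +
    d +                                               # SOS
    (3 * d + d) +                                     # coordinate embedding
    4 * d +                                           # final enc/dec norms
    (3 * d + 3)                                       # head
  expect_identical(nParams(buildTrajViViT(cfg, 1)), as.integer(expected))
})

test_that("causal mask blocks information from future decoder steps", {
  cfg <- tinyConfig(horizon = 4)
  m <- buildTrajViViT(cfg, seed = 2)
  fr <- randFrames(16, 16, 3, seed = 3)
  withr::with_seed(8, {
    tg <- matrix(runif(15, -1, 1), 5, 3)
  })
  base <- forwardTeacherForced(m, fr, tg)
  for (k in 0:3) {
    tg2 <- tg
    tg2[(k + 2):5, ] <- 9  # perturb inputs strictly beyond step k
    pert <- forwardTeacherForced(m, fr, tg2)
    expect_identical(base[seq_len(k + 1), ], pert[seq_len(k + 1), ])
  }
  # step-0 prediction depends only on SOS and the frames
  tg3 <- matrix(5, 5, 3)
  expect_identical(forwardTeacherForced(m, fr, tg3)[1, ], base[1, ])
})

test_that("teacher forcing equals step-by-step ground-truth decoding", {
  cfg <- tinyConfig(horizon = 3)
  m <- buildTrajViViT(cfg, seed = 4)
  fr <- randFrames(16, 16, 3, seed = 5)
  withr::with_seed(6, {
    tg <- matrix(runif(12, -1, 1), 4, 3)
  })
  batched <- forwardTeacherForced(m, fr, tg)
  mem <- drrtrack:::.tv_encode(m, fr)$mem
  stepwise <- matrix(0, 4, 3)
  for (k in 0:3) {
    coords <- tg[seq_len(k), , drop = FALSE]  # ground-truth feedback
    stepwise[k + 1, ] <-
      drrtrack:::.tv_decode(m, mem, coords)$preds[k + 1, ]
  }
  expect_equal(batched, stepwise, tolerance = 1e-6)
})

test_that("autoregressive rollout is consistent and deterministic", {
  cfg <- tinyConfig(horizon = 2)
  m <- buildTrajViViT(cfg, seed = 9)
  fr <- randFrames(16, 16, 3, seed = 1)
  withr::with_seed(2, {
    tg <- matrix(runif(9, -1, 1), 3, 3)
  })
  ar <- forecastAutoregressive(m, fr, 2)
  expect_identical(ar[1, ], forwardTeacherForced(m, fr, tg)[1, ])
  for (T in c(0, 1, 5)) {
    out <- forecastAutoregressive(m, fr, T)
    expect_identical(dim(out), c(as.integer(T + 1), 3L))
    expect_true(all(is.finite(out)))
  }
  expect_identical(forecastAutoregressive(m, fr, 2), ar)
})

test_that("permuting input frames changes the encoder output", {
  cfg <- tinyConfig()
  m <- buildTrajViViT(cfg, seed = 3)
  fr <- randFrames(16, 16, 3, seed = 7)
  mem1 <- drrtrack:::.tv_encode(m, fr)$mem
  mem2 <- drrtrack:::.tv_encode(m, fr[, , c(3, 1, 2)])$mem
  expect_gt(max(abs(mem1 - mem2)), 1e-6)
})

test_that("ConvLSTM hidden state matches hand-computed gate arithmetic", {
  cfg <- modelConfig(imageSize = c(1, 1), patchSize = 1, nPastFrames = 1,
                     horizon = 0, dModel = 4, nHeads = 1, dFfn = 2,
                     nEncLayers = 1, nDecLayers = 1, dropout = 0,
                     convChannels = 1, convKernel = 1)
  m <- buildConvLSTM(cfg, seed = 11)
  x <- array(0.7, c(1, 1, 1))
  p <- m@params$layers$layer1
  z <- 0.7 * p$Wx + p$b            # h and c start at zero
  sig <- function(u) 1 / (1 + exp(-u))
  i <- sig(z[1]); f <- sig(z[2]); g <- tanh(z[3]); o <- sig(z[4])
  h <- o * tanh(i * g)
  expected <- matrix(h * m@params$head$W + rep(m@params$head$b, each = 1),
                     1, 3)
  out <- forecastAutoregressive(m, x)
  expect_equal(out, matrix(as.vector(expected), 1, 3), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tinyConfig()
  fr <- randFrames(16, 16, 3, seed = 13)
  withr::with_seed(14, {
    tg <- matrix(runif(9, -1, 1), 3, 3)
  })
  for (build in list(buildTrajViViT, buildEncoderViT, buildConvLSTM)) {
    m <- build(cfg, seed = 15)
    fwd <- drrtrack:::.model_forward(m, fr, tg, train = FALSE)
    loss0 <- sqrt(mean((fwd$preds - tg)^2))
    dpred <- (fwd$preds - tg) / (length(tg) * loss0)
    g <- drrtrack:::.flatten_params(
      drrtrack:::.model_backward(m, fwd$cache, dpred))
    flat <- drrtrack:::.flatten_params(m@params)
    lossAt <- function(fl) {
      mm <- m
      mm@params <- drrtrack:::.unflatten_into(m@params, fl)
      p <- drrtrack:::.model_forward(mm, fr, tg, train = FALSE)$preds
      sqrt(mean((p - tg)^2))
    }
    withr::with_seed(16, {
      nms <- sample(names(flat), min(8, length(flat)))
    })
    eps <- 1e-6
    for (nm in nms) {
      k <- ((utf8ToInt(substr(nm, 1, 1)) * 7) %% length(flat[[nm]])) + 1
      fp <- flat; fp[[nm]][k] <- fp[[nm]][k] + eps
      fm <- flat; fm[[nm]][k] <- fm[[nm]][k] - eps
      num <- (lossAt(fp) - lossAt(fm)) / (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-4)
    }
  }
})
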