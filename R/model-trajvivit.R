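# Encoder-decoder vision transformer for trajectory forecasting: the
# encoder embeds patch tokens from the past DRR frames under a
# spatio-temporal positional encoding; the decoder autoregressively emits
# normalized 3D positions, seeded by a learned start-of-sequence (SOS)
# vector and conditioned on the encoder memory through cross-attention.

#' Build an encoder-decoder trajectory ViT
#'
#' All weight matrices are Glorot-initialized under the given seed; layer
#' norms start at identity and biases at zero. Decoding is seeded by a
#' learned SOS embedding because no past positions are observed in the
#' markerless setting.
#'
#' @param cfg a configuration from \code{\link{modelConfig}}.
#' @param seed integer seed for the initialization.
#' @return a \linkS4class{ForecastModel} with \code{arch = "trajvivit"}.
#' @export
buildTrajViViT <- function(cfg, seed = 1) {
  d <- cfg$dModel; P <- cfg$patchSize
  params <- withr::with_seed(seed, {
    list(embed = list(W = .glorot(P * P, d), b = numeric(d)),
         enc = stats::setNames(
           lapply(seq_len(cfg$nEncLayers), function(i) .enc_layer_init(d, cfg$dFfn)),
           paste0("layer", seq_len(cfg$nEncLayers))),
         sos = .glorot(1, d),
         coord = list(W = .glorot(3, d), b = numeric(d)),
         dec = stats::setNames(
           lapply(seq_len(cfg$nDecLayers), function(i) .dec_layer_init(d, cfg$dFfn)),
           paste0("layer", seq_len(cfg$nDecLayers))),
         encNorm = list(g = rep(1, d), b = numeric(d)),
         decNorm = list(g = rep(1, d), b = numeric(d)),
         head = list(W = .glorot(d, 3), b = numeric(3)))
  })
  new("ForecastModel", arch = "trajvivit", config = cfg, params = params,
      tags = list(initSeed = seed))
}

# encoder pass: frames (H, W, N) -> memory ((N * Ntok) x d)
.tv_encode <- function(model, framesArr, train = FALSE) {
  cfg <- model@config; p <- model@params
  tok <- patchify(framesArr, cfg$patchSize)
  ntok <- .cfg_ntok(cfg)
  nfr <- dim(framesArr)[3]
  # embeddings scaled by sqrt(d_model) so the additive positional
  # encoding does not dominate the image signal
  X <- .linear_fwd(tok, p$embed$W, p$embed$b) * sqrt(cfg$dModel) +
    positionalEncoding(nfr, ntok, cfg$dModel)
  de <- .dropout_fwd(X, cfg$dropout, train)
  x <- de$y
  caches <- vector("list", cfg$nEncLayers)
  for (l in seq_len(cfg$nEncLayers)) {
    st <- .enc_layer_fwd(x, p$enc[[l]], cfg$nHeads, cfg$dropout, train)
    x <- st$y
    caches[[l]] <- st$cache
  }
  fin <- .ln_fwd(x, p$encNorm$g, p$encNorm$b)
  list(mem = fin$y, cache = list(tok = tok, de = de, layers = caches, fin = fin))
}

.tv_encode_bwd <- function(model, cache, dmem) {
  cfg <- model@config; p <- model@params
  grads <- list(enc = stats::setNames(vector("list", cfg$nEncLayers),
                                      names(p$enc)))
  bf <- .ln_bwd(dmem, cache$fin$cache)
  grads$encNorm <- list(g = bf$dgamma, b = bf$dbeta)
  dx <- bf$dx
  for (l in rev(seq_len(cfg$nEncLayers))) {
    st <- .enc_layer_bwd(dx, cache$layers[[l]], p$enc[[l]])
    dx <- st$dx
    grads$enc[[l]] <- st$grads
  }
  dX <- .dropout_bwd(dx, cache$de$mask) * sqrt(cfg$dModel)
  le <- .linear_bwd(dX, cache$tok, p$embed$W)
  grads$embed <- list(W = le$dW, b = le$db)
  grads
}

# decoder pass: memory + K-1 conditioning coordinates -> K predictions
# (row k predicts offset k - 1; row 1 is conditioned on SOS only)
.tv_decode <- function(model, mem, coordIn, train = FALSE) {
  cfg <- model@config; p <- model@params
  K <- nrow(coordIn) + 1L
  E <- p$sos
  if (K > 1) E <- rbind(E, .linear_fwd(coordIn, p$coord$W, p$coord$b))
  E <- E * sqrt(cfg$dModel) + sinusoidalEncoding(K, cfg$dModel)
  de <- .dropout_fwd(E, cfg$dropout, train)
  y <- de$y
  mask <- lower.tri(matrix(TRUE, K, K), diag = TRUE)
  caches <- vector("list", cfg$nDecLayers)
  for (l in seq_len(cfg$nDecLayers)) {
    st <- .dec_layer_fwd(y, mem, p$dec[[l]], cfg$nHeads, mask,
                         cfg$dropout, train)
    y <- st$y
    caches[[l]] <- st$cache
  }
  fin <- .ln_fwd(y, p$decNorm$g, p$decNorm$b)
  preds <- .linear_fwd(fin$y, p$head$W, p$head$b)
  list(preds = preds,
       cache = list(coordIn = coordIn, de = de, layers = caches, fin = fin))
}

.tv_decode_bwd <- function(model, cache, dpreds) {
  cfg <- model@config; p <- model@params
  lh <- .linear_bwd(dpreds, cache$fin$y, p$head$W)
  bf <- .ln_bwd(lh$dx, cache$fin$cache)
  grads <- list(head = list(W = lh$dW, b = lh$db),
                decNorm = list(g = bf$dgamma, b = bf$dbeta),
                dec = stats::setNames(vector("list", cfg$nDecLayers),
                                      names(p$dec)))
  dy <- bf$dx
  dmem <- NULL
  for (l in rev(seq_len(cfg$nDecLayers))) {
    st <- .dec_layer_bwd(dy, cache$layers[[l]], p$dec[[l]])
    dy <- st$dy
    dmem <- if (is.null(dmem)) st$dmem else dmem + st$dmem
    grads$dec[[l]] <- st$grads
  }
  dE <- .dropout_bwd(dy, cache$de$mask) * sqrt(cfg$dModel)
  grads$sos <- dE[1, , drop = FALSE]
  if (nrow(dE) > 1) {
    lc <- .linear_bwd(dE[-1, , drop = FALSE], cache$coordIn, p$coord$W)
    grads$coord <- list(W = lc$dW, b = lc$db)
  } else {
    grads$coord <- list(W = matrix(0, 3, cfg$dModel), b = numeric(cfg$dModel))
  }
  list(grads = grads, dmem = dmem)
}

#' Teacher-forced forward pass
#'
#' Runs the decoder once on the right-shifted ground-truth positions
#' \code{[SOS, target_0, ..., target_(T-1)]} under a causal mask,
#' returning all T + 1 per-step predictions in a single pass.
#'
#' @param model a "trajvivit" \linkS4class{ForecastModel}.
#' @param framesArr (H, W, N) array of past frames.
#' @param targets (T+1) x 3 matrix of normalized target positions at
#'   offsets 0..T.
#' @return a (T+1) x 3 matrix of predicted normalized positions.
#' @export
forwardTeacherForced <- function(model, framesArr, targets) {
  stopifnot(model@arch == "trajvivit", ncol(targets) == 3)
  enc <- .tv_encode(model, framesArr, train = FALSE)
  Tn <- nrow(targets) - 1L
  coordIn <- targets[seq_len(Tn), , drop = FALSE]
  .tv_decode(model, enc$mem, coordIn, train = FALSE)$preds
}

#' Autoregressive multi-horizon forecast
#'
#' Starts from the learned SOS embedding and feeds each predicted
#' position back as the next decoder input, producing T + 1 positions for
#' offsets 0..T. Deterministic (no dropout at inference).
#'
#' @param model a \linkS4class{ForecastModel} (any architecture; the two
#'   one-shot baselines emit their full output directly).
#' @param framesArr (H, W, N) array of past frames.
#' @param T forecast horizon (>= 0); defaults to the configured horizon.
#'   For the one-shot baselines T is fixed by the trained head.
#' @return a (T+1) x 3 matrix of predicted normalized positions.
#' @export
forecastAutoregressive <- function(model, framesArr, T = model@config$horizon) {
  if (T < 0) stop("T must be >= 0")
  if (model@arch != "trajvivit") {
    if (T != model@config$horizon)
      stop("one-shot baselines predict a fixed horizon")
    return(.model_forward(model, framesArr, targets = NULL, train = FALSE)$preds)
  }
  enc <- .tv_encode(model, framesArr, train = FALSE)
  coords <- matrix(0, 0, 3)
  preds <- NULL
  for (k in 0:T) {
    preds <- .tv_decode(model, enc$mem, coords, train = FALSE)$preds
    if (k < T) coords <- rbind(coords, preds[k + 1L, ])
  }
  preds
}

# unified per-sample forward/backward used by the trainer --------------------

# returns list(preds, cache); for trajvivit the pass is teacher-forced
.model_forward <- function(model, framesArr, targets, train) {
  switch(model@arch,
    trajvivit = {
      enc <- .tv_encode(model, framesArr, train = train)
      Tn <- nrow(targets) - 1L
      coordIn <- targets[seq_len(Tn), , drop = FALSE]
      dec <- .tv_decode(model, enc$mem, coordIn, train = train)
      list(preds = dec$preds, cache = list(enc = enc, dec = dec))
    },
    vit = .vit_forward(model, framesArr, train),
    convlstm = .convlstm_forward(model, framesArr))
}

.model_backward <- function(model, cache, dpreds) {
  switch(model@arch,
    trajvivit = {
      db <- .tv_decode_bwd(model, cache$dec$cache, dpreds)
      ge <- .tv_encode_bwd(model, cache$enc$cache, db$dmem)
      c(ge, db$grads)
    },
    vit = .vit_backward(model, cache, dpreds),
    convlstm = .convlstm_backward(model, cache, dpreds))
}
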