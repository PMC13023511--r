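# Encoder-only ViT baseline: same patch encoder as the encoder-decoder
# model plus a learned CLS token; a linear head regresses the full
# (T+1) x 3 trajectory from the CLS representation in one shot.

#' Build an encoder-only ViT regressor
#'
#' @param cfg a configuration from \code{\link{modelConfig}}; the head
#'   emits 3 * (horizon + 1) outputs.
#' @param seed integer seed for the Glorot initialization.
#' @return a \linkS4class{ForecastModel} with \code{arch = "vit"}.
#' @export
buildEncoderViT <- function(cfg, seed = 1) {
  d <- cfg$dModel; P <- cfg$patchSize
  nout <- 3L * (cfg$horizon + 1L)
  params <- withr::with_seed(seed, {
    list(embed = list(W = .glorot(P * P, d), b = numeric(d)),
         cls = .glorot(1, d),
         enc = stats::setNames(
           lapply(seq_len(cfg$nEncLayers), function(i) .enc_layer_init(d, cfg$dFfn)),
           paste0("layer", seq_len(cfg$nEncLayers))),
         encNorm = list(g = rep(1, d), b = numeric(d)),
         head = list(W = .glorot(d, nout), b = numeric(nout)))
  })
  new("ForecastModel", arch = "vit", config = cfg, params = params,
      tags = list(initSeed = seed))
}

.vit_forward <- function(model, framesArr, train = FALSE) {
  cfg <- model@config; p <- model@params
  tok <- patchify(framesArr, cfg$patchSize)
  ntok <- .cfg_ntok(cfg)
  nfr <- dim(framesArr)[3]
  X <- .linear_fwd(tok, p$embed$W, p$embed$b) * sqrt(cfg$dModel) +
    positionalEncoding(nfr, ntok, cfg$dModel)
  X <- rbind(p$cls * sqrt(cfg$dModel), X)  # CLS token first; learned, no positional term
  de <- .dropout_fwd(X, cfg$dropout, train)
  x <- de$y
  caches <- vector("list", cfg$nEncLayers)
  for (l in seq_len(cfg$nEncLayers)) {
    st <- .enc_layer_fwd(x, p$enc[[l]], cfg$nHeads, cfg$dropout, train)
    x <- st$y
    caches[[l]] <- st$cache
  }
  fin <- .ln_fwd(x, p$encNorm$g, p$encNorm$b)
  out <- .linear_fwd(fin$y[1, , drop = FALSE], p$head$W, p$head$b)
  preds <- matrix(out, cfg$horizon + 1L, 3L)
  list(preds = preds,
       cache = list(tok = tok, de = de, layers = caches, fin = fin))
}

.vit_backward <- function(model, cache, dpreds) {
  cfg <- model@config; p <- model@params
  dout <- matrix(as.vector(dpreds), 1)
  lh <- .linear_bwd(dout, cache$fin$y[1, , drop = FALSE], p$head$W)
  dfin <- matrix(0, nrow(cache$fin$y), ncol(cache$fin$y))
  dfin[1, ] <- lh$dx
  bf <- .ln_bwd(dfin, cache$fin$cache)
  dx <- bf$dx
  grads <- list(head = list(W = lh$dW, b = lh$db),
                encNorm = list(g = bf$dgamma, b = bf$dbeta),
                enc = stats::setNames(vector("list", cfg$nEncLayers),
                                      names(p$enc)))
  for (l in rev(seq_len(cfg$nEncLayers))) {
    st <- .enc_layer_bwd(dx, cache$layers[[l]], p$enc[[l]])
    dx <- st$dx
    grads$enc[[l]] <- st$grads
  }
  dX <- .dropout_bwd(dx, cache$de$mask) * sqrt(cfg$dModel)
  grads$cls <- dX[1, , drop = FALSE]
  le <- .linear_bwd(dX[-1, , drop = FALSE], cache$tok, p$embed$W)
  grads$embed <- list(W = le$dW, b = le$db)
  grads
}
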