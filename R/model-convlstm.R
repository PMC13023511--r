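# Convolutional-LSTM tracker baseline: stacked ConvLSTM layers run over
# the frame sequence; the final hidden state is globally average-pooled
# and mapped to the full (T+1) x 3 trajectory in one shot.

# im2col gather indices for same-padded convolution on an H x W image
.im2col_idx <- function(H, W, k) {
  r <- (k - 1L) %/% 2L
  off <- expand.grid(di = -r:r, dj = -r:r)
  pos <- expand.grid(i = seq_len(H), j = seq_len(W))
  idx <- matrix(0L, H * W, k * k)
  for (m in seq_len(k * k)) {
    ii <- pos$i + off$di[m]; jj <- pos$j + off$dj[m]
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    idx[ok, m] <- (jj[ok] - 1L) * H + ii[ok]
  }
  idx
}

# x: (H*W) x C matrix -> (H*W) x (k^2 * C), channel-major column blocks
.im2col <- function(x, idx) {
  k2 <- ncol(idx); C <- ncol(x)
  nz <- idx > 0L
  out <- matrix(0, nrow(idx), k2 * C)
  for (cc in seq_len(C)) {
    v <- matrix(0, nrow(idx), k2)
    v[nz] <- x[, cc][idx[nz]]
    out[, ((cc - 1L) * k2 + 1L):(cc * k2)] <- v
  }
  out
}

# scatter-add adjoint of .im2col
.col2im <- function(dcol, idx, C) {
  k2 <- ncol(idx)
  out <- matrix(0, nrow(idx), C)
  for (cc in seq_len(C)) {
    dc <- dcol[, ((cc - 1L) * k2 + 1L):(cc * k2), drop = FALSE]
    for (m in seq_len(k2)) {
      nz <- idx[, m] > 0L
      tgt <- idx[nz, m]
      out[tgt, cc] <- out[tgt, cc] + dc[nz, m]
    }
  }
  out
}

.sigm <- function(x) 1 / (1 + exp(-x))

#' Build a ConvLSTM trajectory regressor
#'
#' @param cfg a configuration from \code{\link{modelConfig}};
#'   \code{convChannels} sets the hidden channels per layer and
#'   \code{convKernel} the (odd) kernel size. Forget-gate biases start
#'   at 1, the usual LSTM stabilization.
#' @param seed integer seed for the Glorot initialization.
#' @return a \linkS4class{ForecastModel} with \code{arch = "convlstm"}.
#' @export
buildConvLSTM <- function(cfg, seed = 1) {
  k <- cfg$convKernel
  chans <- cfg$convChannels
  nout <- 3L * (cfg$horizon + 1L)
  params <- withr::with_seed(seed, {
    layers <- list()
    cin <- 1L
    for (l in seq_along(chans)) {
      ch <- chans[l]
      b <- numeric(4 * ch)
      b[(ch + 1):(2 * ch)] <- 1  # forget gate bias
      layers[[paste0("layer", l)]] <-
        list(Wx = .glorot(k * k * cin, 4 * ch),
             Wh = .glorot(k * k * ch, 4 * ch), b = b)
      cin <- ch
    }
    list(layers = layers,
         head = list(W = .glorot(chans[length(chans)], nout),
                     b = numeric(nout)))
  })
  new("ForecastModel", arch = "convlstm", config = cfg, params = params,
      tags = list(initSeed = seed))
}

# one ConvLSTM cell step; returns new state and a cache for BPTT
.clstm_step <- function(xcol, hcol, cPrev, p, ch) {
  z <- sweep(xcol %*% p$Wx + hcol %*% p$Wh, 2, p$b, "+")
  i <- .sigm(z[, 1:ch, drop = FALSE])
  f <- .sigm(z[, (ch + 1):(2 * ch), drop = FALSE])
  g <- tanh(z[, (2 * ch + 1):(3 * ch), drop = FALSE])
  o <- .sigm(z[, (3 * ch + 1):(4 * ch), drop = FALSE])
  cNew <- f * cPrev + i * g
  tc <- tanh(cNew)
  h <- o * tc
  list(h = h, c = cNew,
       cache = list(xcol = xcol, hcol = hcol, cPrev = cPrev,
                    i = i, f = f, g = g, o = o, tc = tc))
}

.convlstm_forward <- function(model, framesArr) {
  cfg <- model@config; p <- model@params
  d <- dim(framesArr)
  H <- d[1]; W <- d[2]; N <- d[3]
  npx <- H * W
  idx <- .im2col_idx(H, W, cfg$convKernel)
  xseq <- lapply(seq_len(N), function(t) matrix(framesArr[, , t], ncol = 1))
  layerCaches <- vector("list", length(p$layers))
  for (l in seq_along(p$layers)) {
    ch <- cfg$convChannels[l]
    h <- matrix(0, npx, ch); cc <- matrix(0, npx, ch)
    caches <- vector("list", N)
    hseq <- vector("list", N)
    for (t in seq_len(N)) {
      st <- .clstm_step(.im2col(xseq[[t]], idx), .im2col(h, idx), cc,
                        p$layers[[l]], ch)
      h <- st$h; cc <- st$c
      caches[[t]] <- st$cache
      hseq[[t]] <- h
    }
    layerCaches[[l]] <- caches
    xseq <- hseq
  }
  hLast <- xseq[[N]]
  pooled <- matrix(colMeans(hLast), 1)
  out <- .linear_fwd(pooled, p$head$W, p$head$b)
  preds <- matrix(out, cfg$horizon + 1L, 3L)
  list(preds = preds,
       cache = list(idx = idx, layerCaches = layerCaches, pooled = pooled,
                    npx = npx, N = N))
}

.convlstm_backward <- function(model, cache, dpreds) {
  cfg <- model@config; p <- model@params
  idx <- cache$idx; npx <- cache$npx; N <- cache$N
  lh <- .linear_bwd(matrix(as.vector(dpreds), 1), cache$pooled, p$head$W)
  grads <- list(head = list(W = lh$dW, b = lh$db), layers = list())
  nl <- length(p$layers)
  # gradient w.r.t. each layer's hidden-state sequence, top layer first
  dhseq <- vector("list", nl)
  for (l in seq_len(nl)) {
    ch <- cfg$convChannels[l]
    dhseq[[l]] <- lapply(seq_len(N), function(t) matrix(0, npx, ch))
  }
  dhseq[[nl]][[N]] <- matrix(rep(lh$dx / npx, each = npx), npx)
  for (l in rev(seq_len(nl))) {
    ch <- cfg$convChannels[l]
    pl <- p$layers[[l]]
    dWx <- matrix(0, nrow(pl$Wx), ncol(pl$Wx))
    dWh <- matrix(0, nrow(pl$Wh), ncol(pl$Wh))
    db <- numeric(length(pl$b))
    dhNext <- matrix(0, npx, ch)  # via recurrent connection
    dcNext <- matrix(0, npx, ch)
    for (t in rev(seq_len(N))) {
      cc <- cache$layerCaches[[l]][[t]]
      dh <- dhseq[[l]][[t]] + dhNext
      dc <- dcNext + dh * cc$o * (1 - cc$tc^2)
      do <- dh * cc$tc
      di <- dc * cc$g
      df <- dc * cc$cPrev
      dg <- dc * cc$i
      dcNext <- dc * cc$f
      dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
      dWx <- dWx + crossprod(cc$xcol, dz)
      dWh <- dWh + crossprod(cc$hcol, dz)
      db <- db + colSums(dz)
      dhNext <- .col2im(dz %*% t(pl$Wh), idx, ch)
      if (l > 1) {
        cin <- cfg$convChannels[l - 1]
        dxl <- .col2im(dz %*% t(pl$Wx), idx, cin)
        dhseq[[l - 1]][[t]] <- dhseq[[l - 1]][[t]] + dxl
      }
    }
    grads$layers[[names(p$layers)[l]]] <- list(Wx = dWx, Wh = dWh, b = db)
  }
  grads$layers <- grads$layers[names(p$layers)]
  grads
}
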