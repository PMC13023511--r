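# Neural-network primitives: parameter trees, Glorot initialization,
# linear / layer-norm / feed-forward / multi-head-attention layers with
# hand-derived backward passes, dropout, and sinusoidal positional
# encodings. Everything operates on plain numeric matrices (rows =
# tokens, columns = features), so BLAS does the heavy lifting.

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# ---- parameter trees ------------------------------------------------------

# flatten a nested named list of arrays into a flat named list with
# dot-separated path names
.flatten_params <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      if (is.null(x[[nm]])) next
      out <- c(out, .flatten_params(x[[nm]], paste0(prefix, nm, ".")))
    }
    out
  } else {
    stats::setNames(list(x), substr(prefix, 1, nchar(prefix) - 1))
  }
}

.unflatten_into <- function(skeleton, flat) {
  for (nm in names(flat)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    skeleton[[path]] <- flat[[nm]]
  }
  skeleton
}

# elementwise sum of two parallel flat lists
.flat_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

.flat_scale <- function(a, s) lapply(a, function(x) x * s)

.has_lora <- function(params) {
  any(grepl("\\.lora\\.", names(.flatten_params(params))))
}

# ---- elementary layers ----------------------------------------------------

.linear_fwd <- function(x, W, b) {
  y <- x %*% W
  if (!is.null(b)) y <- sweep(y, 2, b, "+")
  y
}

.linear_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

.LN_EPS <- 1e-5

.ln_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

.ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

.softmax_bwd <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

.dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim(x))
  list(y = x * mask, mask = mask)
}

.dropout_bwd <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- multi-head attention -------------------------------------------------

.attn_init <- function(d) {
  list(Wq = .glorot(d, d), Wk = .glorot(d, d), Wv = .glorot(d, d),
       Wo = .glorot(d, d), bq = numeric(d), bk = numeric(d),
       bv = numeric(d), bo = numeric(d))
}

# effective Q/V projection weights including any LoRA adapters
.attn_eff <- function(p) {
  Wq <- p$Wq; Wv <- p$Wv
  if (!is.null(p$lora)) {
    s <- p$lora$scale
    Wq <- Wq + s * (p$lora$qA %*% p$lora$qB)
    Wv <- Wv + s * (p$lora$vA %*% p$lora$vB)
  }
  list(Wq = Wq, Wv = Wv)
}

# qx: query tokens (n x d); kx: key/value tokens (m x d); mask: optional
# n x m logical matrix, TRUE where attention is allowed
.attn_fwd <- function(qx, kx, p, nheads, mask = NULL) {
  eff <- .attn_eff(p)
  Q <- .linear_fwd(qx, eff$Wq, p$bq)
  K <- .linear_fwd(kx, p$Wk, p$bk)
  V <- .linear_fwd(kx, eff$Wv, p$bv)
  d <- ncol(Q); dh <- d %/% nheads
  O <- matrix(0, nrow(Q), d)
  Ph <- vector("list", nheads)
  for (h in seq_len(nheads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    if (!is.null(mask)) S[!mask] <- -Inf
    P <- .softmax_rows(S)
    Ph[[h]] <- P
    O[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  out <- .linear_fwd(O, p$Wo, p$bo)
  list(y = out,
       cache = list(qx = qx, kx = kx, Q = Q, K = K, V = V, O = O, Ph = Ph,
                    eff = eff, nheads = nheads, dh = dh))
}

.attn_bwd <- function(dy, cache, p) {
  nheads <- cache$nheads; dh <- cache$dh
  lo <- .linear_bwd(dy, cache$O, p$Wo)
  dO <- lo$dx
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(nheads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- cache$Ph[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    dP <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(P, dOh)
    dS <- .softmax_bwd(dP, P) / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  lq <- .linear_bwd(dQ, cache$qx, cache$eff$Wq)
  lk <- .linear_bwd(dK, cache$kx, p$Wk)
  lv <- .linear_bwd(dV, cache$kx, cache$eff$Wv)
  grads <- list(Wq = lq$dW, Wk = lk$dW, Wv = lv$dW, Wo = lo$dW,
                bq = lq$db, bk = lk$db, bv = lv$db, bo = lo$db)
  if (!is.null(p$lora)) {
    s <- p$lora$scale
    grads$lora <- list(
      qA = s * (lq$dW %*% t(p$lora$qB)), qB = s * (t(p$lora$qA) %*% lq$dW),
      vA = s * (lv$dW %*% t(p$lora$vB)), vB = s * (t(p$lora$vA) %*% lv$dW),
      scale = 0)
  }
  list(dq = lq$dx, dk = lk$dx + lv$dx, grads = grads)
}

# ---- feed-forward ---------------------------------------------------------

.ffn_init <- function(d, dff) {
  list(W1 = .glorot(d, dff), b1 = numeric(dff),
       W2 = .glorot(dff, d), b2 = numeric(d))
}

.ffn_fwd <- function(x, p) {
  a <- .linear_fwd(x, p$W1, p$b1)
  h <- pmax(a, 0)
  y <- .linear_fwd(h, p$W2, p$b2)
  list(y = y, cache = list(x = x, a = a, h = h))
}

.ffn_bwd <- function(dy, cache, p) {
  l2 <- .linear_bwd(dy, cache$h, p$W2)
  dh <- l2$dx
  da <- dh * (cache$a > 0)
  l1 <- .linear_bwd(da, cache$x, p$W1)
  list(dx = l1$dx,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

# ---- transformer layers ----------------------------------------------------
# Pre-layer-norm residual blocks (the ViT convention): each sub-layer
# normalizes its input, and a final norm closes the stack. Pre-LN keeps
# gradients well-scaled at small step budgets.

.enc_layer_init <- function(d, dff) {
  list(attn = .attn_init(d),
       ln1 = list(g = rep(1, d), b = numeric(d)),
       ffn = .ffn_init(d, dff),
       ln2 = list(g = rep(1, d), b = numeric(d)))
}

.enc_layer_fwd <- function(x, p, nheads, dropout, train) {
  n1 <- .ln_fwd(x, p$ln1$g, p$ln1$b)
  at <- .attn_fwd(n1$y, n1$y, p$attn, nheads)
  d1 <- .dropout_fwd(at$y, dropout, train)
  x1 <- x + d1$y
  n2 <- .ln_fwd(x1, p$ln2$g, p$ln2$b)
  ff <- .ffn_fwd(n2$y, p$ffn)
  d2 <- .dropout_fwd(ff$y, dropout, train)
  list(y = x1 + d2$y,
       cache = list(n1 = n1, at = at, d1 = d1, n2 = n2, ff = ff, d2 = d2))
}

.enc_layer_bwd <- function(dy, cache, p) {
  dff <- .dropout_bwd(dy, cache$d2$mask)
  fb <- .ffn_bwd(dff, cache$ff$cache, p$ffn)
  b2 <- .ln_bwd(fb$dx, cache$n2$cache)
  dx1 <- dy + b2$dx
  datt <- .dropout_bwd(dx1, cache$d1$mask)
  ab <- .attn_bwd(datt, cache$at$cache, p$attn)
  b1 <- .ln_bwd(ab$dq + ab$dk, cache$n1$cache)
  list(dx = dx1 + b1$dx,
       grads = list(attn = ab$grads,
                    ln1 = list(g = b1$dgamma, b = b1$dbeta),
                    ffn = fb$grads,
                    ln2 = list(g = b2$dgamma, b = b2$dbeta)))
}

.dec_layer_init <- function(d, dff) {
  list(self = .attn_init(d),
       ln1 = list(g = rep(1, d), b = numeric(d)),
       cross = .attn_init(d),
       ln2 = list(g = rep(1, d), b = numeric(d)),
       ffn = .ffn_init(d, dff),
       ln3 = list(g = rep(1, d), b = numeric(d)))
}

.dec_layer_fwd <- function(y, mem, p, nheads, mask, dropout, train) {
  n1 <- .ln_fwd(y, p$ln1$g, p$ln1$b)
  a1 <- .attn_fwd(n1$y, n1$y, p$self, nheads, mask)
  d1 <- .dropout_fwd(a1$y, dropout, train)
  y1 <- y + d1$y
  n2 <- .ln_fwd(y1, p$ln2$g, p$ln2$b)
  a2 <- .attn_fwd(n2$y, mem, p$cross, nheads)
  d2 <- .dropout_fwd(a2$y, dropout, train)
  y2 <- y1 + d2$y
  n3 <- .ln_fwd(y2, p$ln3$g, p$ln3$b)
  ff <- .ffn_fwd(n3$y, p$ffn)
  d3 <- .dropout_fwd(ff$y, dropout, train)
  list(y = y2 + d3$y,
       cache = list(n1 = n1, a1 = a1, d1 = d1, n2 = n2, a2 = a2, d2 = d2,
                    n3 = n3, ff = ff, d3 = d3))
}

.dec_layer_bwd <- function(dy, cache, p) {
  dff <- .dropout_bwd(dy, cache$d3$mask)
  fb <- .ffn_bwd(dff, cache$ff$cache, p$ffn)
  b3 <- .ln_bwd(fb$dx, cache$n3$cache)
  dy2 <- dy + b3$dx
  dcross <- .dropout_bwd(dy2, cache$d2$mask)
  cb <- .attn_bwd(dcross, cache$a2$cache, p$cross)
  b2 <- .ln_bwd(cb$dq, cache$n2$cache)
  dy1 <- dy2 + b2$dx
  dself <- .dropout_bwd(dy1, cache$d1$mask)
  sb <- .attn_bwd(dself, cache$a1$cache, p$self)
  b1 <- .ln_bwd(sb$dq + sb$dk, cache$n1$cache)
  list(dy = dy1 + b1$dx, dmem = cb$dk,
       grads = list(self = sb$grads,
                    ln1 = list(g = b1$dgamma, b = b1$dbeta),
                    cross = cb$grads,
                    ln2 = list(g = b2$dgamma, b = b2$dbeta),
                    ffn = fb$grads,
                    ln3 = list(g = b3$dgamma, b = b3$dbeta)))
}

# ---- positional encodings -------------------------------------------------

#' Fixed sinusoidal encoding table
#'
#' Standard transformer sinusoids: for position p (0-based) and feature
#' pair i, \code{sin(p / 10000^(2i/d))} and \code{cos(p / 10000^(2i/d))}.
#'
#' @param npos number of positions (>= 1).
#' @param d encoding dimension (even).
#' @return an npos x d matrix; row k encodes position k - 1.
#' @export
sinusoidalEncoding <- function(npos, d) {
  stopifnot(npos >= 1, d >= 2, d %% 2 == 0)
  pos <- seq_len(npos) - 1
  i <- seq_len(d %/% 2) - 1
  div <- 10000^(2 * i / d)
  ang <- outer(pos, 1 / div)
  pe <- matrix(0, npos, d)
  pe[, seq(1, d, by = 2)] <- sin(ang)
  pe[, seq(2, d, by = 2)] <- cos(ang)
  pe
}

#' Spatio-temporal positional encoding for patch tokens
#'
#' Additive factorized encoding for tokens ordered (frame, patch): a
#' temporal sinusoid indexed by frame occupies the first half of the
#' feature channels and a spatial sinusoid indexed by patch the second
#' half, so the encoding is the sum of a purely temporal and a purely
#' spatial term and every (frame, patch) pair receives a distinct
#' vector. Values are bounded by [-2, 2].
#'
#' @param nFrames number of frames (>= 1).
#' @param nPatches number of patches per frame (>= 1).
#' @param d model dimension (divisible by 4).
#' @return an (nFrames * nPatches) x d matrix, frame-major token order.
#' @export
positionalEncoding <- function(nFrames, nPatches, d) {
  stopifnot(nFrames >= 1, nPatches >= 1, d %% 4 == 0)
  h <- d %/% 2
  Tt <- cbind(sinusoidalEncoding(nFrames, h), matrix(0, nFrames, h))
  Ss <- cbind(matrix(0, nPatches, h), sinusoidalEncoding(nPatches, h))
  Tt[rep(seq_len(nFrames), each = nPatches), , drop = FALSE] +
    Ss[rep(seq_len(nPatches), times = nFrames), , drop = FALSE]
}
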