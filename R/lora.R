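# Low-rank adaptation (LoRA): rank-r adapters on the query and value
# projections of every attention block. The base weights are frozen; the
# adapters start at exact identity (B = 0), so the adapted model equals
# the frozen model until the first optimizer step.

#' Create a LoRA fine-tuning configuration
#'
#' @param rank adapter rank r (>= 1).
#' @param alpha scaling numerator; the adapter contribution is
#'   \code{(alpha / rank) * A \%*\% B}. Default alpha = rank.
#' @param lr constant fine-tuning learning rate (default 1e-2).
#' @param epochs passes over the shot set (default 50).
#' @param seed integer seed for adapter initialization and shuffling.
#' @return a validated configuration list.
#' @export
loraConfig <- function(rank = 8, alpha = rank, lr = 1e-2, epochs = 50,
                       seed = 1) {
  if (rank < 1) stop("rank must be >= 1")
  if (lr <= 0) stop("lr must be positive")
  list(rank = as.integer(rank), alpha = alpha, lr = lr,
       epochs = as.integer(epochs), seed = seed)
}

# attach adapters to one attention-parameter block
.attn_add_lora <- function(p, rank, alpha) {
  d <- nrow(p$Wq)
  p$lora <- list(qA = .glorot(d, rank), qB = matrix(0, rank, d),
                 vA = .glorot(d, rank), vB = matrix(0, rank, d),
                 scale = alpha / rank)
  p
}

#' Attach zero-initialized LoRA adapters to a model
#'
#' Adds rank-r adapters to the Q and V projections of every attention
#' block (encoder self-attention and, for the encoder-decoder model,
#' decoder self- and cross-attention). A is Glorot-initialized, B is
#' zero, so the adapted model's outputs are bit-identical to the base
#' model's until training updates the adapters.
#'
#' @param model a "trajvivit" or "vit" \linkS4class{ForecastModel}.
#' @param cfg a \code{\link{loraConfig}}.
#' @return the model with adapters attached.
#' @export
addLoraAdapters <- function(model, cfg = loraConfig()) {
  if (model@arch == "convlstm")
    stop("LoRA adapters target attention projections; not applicable to ConvLSTM")
  withr::with_seed(cfg$seed, {
    for (l in seq_along(model@params$enc))
      model@params$enc[[l]]$attn <-
        .attn_add_lora(model@params$enc[[l]]$attn, cfg$rank, cfg$alpha)
    if (model@arch == "trajvivit") {
      for (l in seq_along(model@params$dec)) {
        model@params$dec[[l]]$self <-
          .attn_add_lora(model@params$dec[[l]]$self, cfg$rank, cfg$alpha)
        model@params$dec[[l]]$cross <-
          .attn_add_lora(model@params$dec[[l]]$cross, cfg$rank, cfg$alpha)
      }
    }
  })
  model@tags$lora <- cfg
  model
}

#' Fine-tune a pre-trained model with LoRA on a few shots
#'
#' Freezes all base weights, attaches zero-initialized rank-r adapters,
#' and trains only the adapters with Adam at the constant fine-tuning
#' learning rate on the given patient-specific samples.
#'
#' @param model a pre-trained \linkS4class{ForecastModel}.
#' @param shots a \linkS4class{ForecastSampleSet} with the patient's
#'   annotated treatment samples (n >= 1).
#' @param cfg a \code{\link{loraConfig}}.
#' @param batchSize mini-batch size (default: all shots up to 12).
#' @return as \code{\link{trainModel}}; models are tagged
#'   \code{strategy = "FT"} with the shot count.
#' @export
finetuneLoRA <- function(model, shots, cfg = loraConfig(), batchSize = NULL) {
  sets <- .as_set_list(shots)
  nShots <- sum(vapply(sets, length, integer(1)))
  if (nShots < 1) stop("need at least one fine-tuning shot")
  if (is.null(batchSize)) batchSize <- min(12L, nShots)
  model <- addLoraAdapters(model, cfg)
  trainable <- grep("\\.lora\\.(qA|qB|vA|vB)$",
                    names(.flatten_params(model@params)), value = TRUE)
  tc <- trainConfig(epochs = cfg$epochs, batchSize = batchSize,
                    peakLr = cfg$lr, seed = cfg$seed)
  res <- trainModel(model, shots, tc, trainable = trainable,
                    schedule = "constant")
  for (nm in c("model", "bestModel")) {
    res[[nm]]@tags$strategy <- "FT"
    res[[nm]]@tags$nShots <- nShots
  }
  res
}

#' Fold LoRA adapters into the base weights
#'
#' Returns an adapter-free model whose Q/V projections equal
#' \code{W + (alpha/r) A B}; useful before checkpointing.
#'
#' @param model a model with adapters attached.
#' @return the merged \linkS4class{ForecastModel}.
#' @export
mergeLora <- function(model) {
  mergeAttn <- function(p) {
    if (is.null(p$lora)) return(p)
    eff <- .attn_eff(p)
    p$Wq <- eff$Wq; p$Wv <- eff$Wv
    p$lora <- NULL
    p
  }
  for (l in seq_along(model@params$enc))
    model@params$enc[[l]]$attn <- mergeAttn(model@params$enc[[l]]$attn)
  for (l in seq_along(model@params$dec)) {
    model@params$dec[[l]]$self <- mergeAttn(model@params$dec[[l]]$self)
    model@params$dec[[l]]$cross <- mergeAttn(model@params$dec[[l]]$cross)
  }
  model@tags$lora <- NULL
  model
}
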