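# The network: five conv blocks (ReLU, max-pool) compress L bp of one-hot
# sequence into L/binSize tokens of seqChannels features; the TF block is
# concatenated to give dModel-wide tokens; a learned absolute position
# embedding is added; nLayers post-norm transformer encoder layers follow;
# a linear (or linear+sigmoid) head emits K signals per token. The whole
# forward pass is built on the autodiff tape so training, attribution
# gradients and attention capture share one code path.

#' Build a ModelConfig
#'
#' Defaults give a desk-scale model. Use \code{profile = "paper"} for the
#' published-scale architecture (128 kb input, 128-bp bins, C = 256,
#' 712-wide TF features, d_model = 968, 8 heads of width 121, 12 layers).
#'
#' @param profile "toy" or "paper" preset; individual arguments override.
#' @param inputLength input window length L (bp).
#' @param binSize token width N (bp); tokens = L/N.
#' @param seqChannels sequence-embedding channels C.
#' @param nTF number of TFs before padding.
#' @param nTFPadded TF feature width (default: next even value).
#' @param nHeads,nLayers transformer shape.
#' @param nSignals output tracks K.
#' @param headType "regression" or "classification".
#' @param poolFactors five pool factors multiplying to \code{binSize}.
#' @param convChannels five conv output channel counts (last must equal C).
#' @param convKernel conv kernel width.
#' @param ffnMult feed-forward width multiplier.
#' @return A \code{\linkS4class{ModelConfig}}.
#' @examples
#' cfg <- modelConfig("paper")
#' nTokens(cfg)        # 1000
#' dModel(cfg)         # 968
#' headDim(cfg)        # 121
#' @export
modelConfig <- function(profile = c("toy", "paper"),
                        inputLength = NULL, binSize = NULL,
                        seqChannels = NULL, nTF = NULL, nTFPadded = NULL,
                        nHeads = NULL, nLayers = NULL, nSignals = NULL,
                        headType = "regression", poolFactors = NULL,
                        convChannels = NULL, convKernel = NULL,
                        ffnMult = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") {
    list(inputLength = 128000, binSize = 128, seqChannels = 256L, nTF = 711L,
         nHeads = 8L, nLayers = 12L, nSignals = 8L,
         poolFactors = c(2, 2, 2, 4, 4),
         convChannels = c(64L, 128L, 128L, 256L, 256L),
         convKernel = 9L, ffnMult = 4)
  } else {
    list(inputLength = 4096, binSize = 128, seqChannels = 8L, nTF = 8L,
         nHeads = 2L, nLayers = 2L, nSignals = 8L,
         poolFactors = c(2, 2, 2, 4, 4),
         convChannels = c(8L, 8L, 8L, 8L, 8L),
         convKernel = 5L, ffnMult = 2)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  nTF <- as.integer(pick(nTF, def$nTF))
  seqChannels <- as.integer(pick(seqChannels, def$seqChannels))
  convChannels <- as.integer(pick(convChannels, {
    cc <- def$convChannels; cc[length(cc)] <- seqChannels; cc
  }))
  new("ModelConfig",
      inputLength = pick(inputLength, def$inputLength),
      binSize = pick(binSize, def$binSize),
      seqChannels = seqChannels, nTF = nTF,
      nTFPadded = as.integer(pick(nTFPadded, padTFWidth(nTF))),
      nHeads = as.integer(pick(nHeads, def$nHeads)),
      nLayers = as.integer(pick(nLayers, def$nLayers)),
      nSignals = as.integer(pick(nSignals, def$nSignals)),
      headType = headType,
      poolFactors = pick(poolFactors, def$poolFactors),
      convChannels = convChannels,
      convKernel = as.integer(pick(convKernel, def$convKernel)),
      ffnMult = pick(ffnMult, def$ffnMult))
}

#' @describeIn modelConfig token embedding width C + nTFPadded.
#' @param config a \code{ModelConfig}.
#' @export
dModel <- function(config) config@seqChannels + config@nTFPadded

#' @describeIn modelConfig number of tokens L/N.
#' @export
nTokens <- function(config) as.integer(config@inputLength %/% config@binSize)

#' @describeIn modelConfig per-head width d_K = d_V = dModel/nHeads.
#' @export
headDim <- function(config) as.integer(dModel(config) %/% config@nHeads)

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0(
    "ModelConfig: L=%d bp, %d tokens of %d bp | dModel=%d (C=%d + TF %d)\n",
    "  %d heads x width %d, %d layers, %d signals, %s head\n"),
    object@inputLength, nTokens(object), object@binSize, dModel(object),
    object@seqChannels, object@nTFPadded, object@nHeads, headDim(object),
    object@nLayers, object@nSignals, object@headType))
})

# Xavier-style init.
rmat <- function(n, k) matrix(stats::rnorm(n * k, sd = sqrt(2 / (n + k))), n, k)

#' Initialize a model
#'
#' @param config a \code{ModelConfig}.
#' @param seed RNG seed for the weight draw.
#' @return An \code{\linkS4class{EpiModel}}.
#' @export
initModel <- function(config, seed = 1L) {
  stopifnot(validObject(config))
  set.seed(seed)
  d <- dModel(config)
  dk <- headDim(config)
  p <- list()
  cin <- 4L
  for (b in seq_along(config@convChannels)) {
    cout <- config@convChannels[b]
    p[[sprintf("conv%d_W", b)]] <- rmat(config@convKernel * cin, cout)
    p[[sprintf("conv%d_b", b)]] <- numeric(cout)
    cin <- cout
  }
  p[["pos"]] <- matrix(stats::rnorm(nTokens(config) * d, sd = 0.02),
                       nTokens(config), d)
  ff <- as.integer(round(config@ffnMult * d))
  for (l in seq_len(config@nLayers)) {
    for (h in seq_len(config@nHeads)) {
      p[[sprintf("L%d_h%d_Wq", l, h)]] <- rmat(d, dk)
      p[[sprintf("L%d_h%d_Wk", l, h)]] <- rmat(d, dk)
      p[[sprintf("L%d_h%d_Wv", l, h)]] <- rmat(d, dk)
    }
    p[[sprintf("L%d_Wo", l)]] <- rmat(d, d)
    p[[sprintf("L%d_bo", l)]] <- numeric(d)
    p[[sprintf("L%d_ln1_g", l)]] <- rep(1, d)
    p[[sprintf("L%d_ln1_b", l)]] <- numeric(d)
    p[[sprintf("L%d_ffn_W1", l)]] <- rmat(d, ff)
    p[[sprintf("L%d_ffn_b1", l)]] <- numeric(ff)
    p[[sprintf("L%d_ffn_W2", l)]] <- rmat(ff, d)
    p[[sprintf("L%d_ffn_b2", l)]] <- numeric(d)
    p[[sprintf("L%d_ln2_g", l)]] <- rep(1, d)
    p[[sprintf("L%d_ln2_b", l)]] <- numeric(d)
  }
  p[["head_W"]] <- rmat(d, config@nSignals)
  p[["head_b"]] <- numeric(config@nSignals)
  new("EpiModel", config = config, params = p)
}

setMethod("show", "EpiModel", function(object) {
  cat(sprintf("EpiModel with %s trainable parameters\n",
              format(countParameters(object), big.mark = ",")))
  show(object@config)
})

#' @describeIn initModel total trainable scalar count of a model.
#' @param x an \code{EpiModel} or \code{ModelConfig}.
#' @export
setMethod("countParameters", "EpiModel", function(x)
  sum(vapply(x@params, length, 1L)))

#' @describeIn initModel parameter count implied by a config, computed from
#'   the architecture arithmetic without allocating weights (usable at the
#'   published scale).
#' @export
setMethod("countParameters", "ModelConfig", function(x) {
  d <- dModel(x); dk <- headDim(x); tk <- nTokens(x)
  ff <- round(x@ffnMult * d)
  cin <- 4
  conv <- 0
  for (cout in x@convChannels) {
    conv <- conv + x@convKernel * cin * cout + cout
    cin <- cout
  }
  perLayer <- 3 * x@nHeads * d * dk + d * d + d + 2 * d +
    d * ff + ff + ff * d + d + 2 * d
  conv + tk * d + x@nLayers * perLayer + d * x@nSignals + x@nSignals
})

# Leaf nodes for every parameter on a fresh tape.
paramLeaves <- function(tape, params) lapply(params, function(p) adLeaf(tape, p))

# Tape-building forward pass. onehot may be a constant matrix; tfInput may
# be a constant or a leaf node (leaf when input gradients are wanted, e.g.
# for gradient importance scores).
forwardTape <- function(config, pn, onehot, tfInput, tape,
                        wantAttention = FALSE) {
  if (nrow(adVal(onehot)) != config@inputLength)
    stop(sprintf("input length %d does not match config L=%d",
                 nrow(adVal(onehot)), config@inputLength))
  h <- onehot
  for (b in seq_along(config@convChannels)) {
    h <- adConv1d(h, pn[[sprintf("conv%d_W", b)]], pn[[sprintf("conv%d_b", b)]],
                  config@convKernel)
    h <- adReLU(h)
    h <- adMaxPool(h, config@poolFactors[b])
  }
  seqEmb <- h                                   # tokens x C
  x <- adCbind(seqEmb, tfInput)                 # tokens x dModel
  enc <- encoderTape(config, pn, x, wantAttention)
  pred <- adAdd(adMatmul(enc$x, pn[["head_W"]]), pn[["head_b"]])
  if (config@headType == "classification") pred <- adSigmoid(pred)
  list(seqEmb = seqEmb, hidden = enc$x, pred = pred, attn = enc$attn,
       tape = tape)
}

# Assemble an AttentionSummary from captured attention nodes.
attentionSummaryFromNodes <- function(attn, lastNLayers = 1L) {
  mats <- lapply(attn, function(layer) lapply(layer, adVal))
  all <- unlist(mats, recursive = FALSE)
  meanA <- Reduce(`+`, all) / length(all)
  li <- seq(length(mats) - lastNLayers + 1L, length(mats))
  last <- unlist(mats[li], recursive = FALSE)
  lastA <- Reduce(`+`, last) / length(last)
  new("AttentionSummary", attention = mats, meanAttention = meanA,
      lastAttention = lastA, lastNLayers = as.integer(lastNLayers))
}

#' @describeIn predictSignals average attention over all layers and heads.
#' @export
setMethod("meanAttention", "AttentionSummary", function(x) x@meanAttention)

#' @describeIn predictSignals head-averaged attention of the last layer(s),
#'   the matrix the contact-guidance loss constrains.
#' @export
setMethod("lastLayerAttention", "AttentionSummary", function(x) x@lastAttention)

setMethod("show", "AttentionSummary", function(object) {
  cat(sprintf("AttentionSummary: %d layers x %d heads, %d tokens\n",
              length(object@attention), length(object@attention[[1]]),
              nrow(object@meanAttention)))
})

#' Sequence module: one-hot DNA to token embeddings
#'
#' Five conv blocks (convolution, ReLU, max-pool) whose pool factors
#' multiply to the bin size, so an L x 4 one-hot matrix becomes an
#' (L/binSize) x seqChannels embedding (1000 x 256 at the published scale).
#'
#' @param model an \code{EpiModel}.
#' @param onehot L x 4 one-hot matrix.
#' @return tokens x seqChannels matrix.
#' @export
sequenceEmbed <- function(model, onehot) {
  tape <- adTape()
  pn <- paramLeaves(tape, model@params)
  h <- onehot
  for (b in seq_along(model@config@convChannels)) {
    h <- adConv1d(h, pn[[sprintf("conv%d_W", b)]], pn[[sprintf("conv%d_b", b)]],
                  model@config@convKernel)
    h <- adReLU(h)
    h <- adMaxPool(h, model@config@poolFactors[b])
  }
  adVal(h)
}

#' Token assembly: concatenate sequence and TF features
#'
#' @param seqEmb tokens x C sequence embedding.
#' @param tfBlock tokens x nTFPadded combined TF features
#'   (\code{\link{combineTF}}).
#' @return tokens x (C + nTFPadded) matrix.
#' @export
assembleTokens <- function(seqEmb, tfBlock) {
  if (nrow(seqEmb) != nrow(tfBlock))
    stop(sprintf("token count mismatch: %d vs %d", nrow(seqEmb), nrow(tfBlock)))
  cbind(seqEmb, tfBlock)
}

#' Transformer encoder over assembled tokens
#'
#' Adds the learned absolute position embedding, then applies the encoder
#' stack (multi-head self-attention with softmax(QK^T/sqrt(d_k))V, add &
#' norm, feed-forward, add & norm).
#'
#' @param model an \code{EpiModel}.
#' @param tokens tokens x dModel matrix from \code{\link{assembleTokens}}.
#' @param returnAttention capture per-layer, per-head attention matrices.
#' @param lastNLayers trailing layers entering the head-averaged attention.
#' @return list with \code{hidden} (tokens x dModel) and, if requested,
#'   \code{attention} (an \code{\linkS4class{AttentionSummary}}).
#' @export
transformerForward <- function(model, tokens, returnAttention = FALSE,
                               lastNLayers = 1L) {
  cfg <- model@config
  if (ncol(tokens) != dModel(cfg))
    stop(sprintf("token width %d does not match dModel %d",
                 ncol(tokens), dModel(cfg)))
  # reuse forwardTape's encoder by splitting tokens back into its two parts
  C <- cfg@seqChannels
  tape <- adTape()
  pn <- paramLeaves(tape, model@params)
  res <- encoderTape(cfg, pn, adLeaf(tape, tokens), returnAttention)
  out <- list(hidden = adVal(res$x))
  if (returnAttention)
    out$attention <- attentionSummaryFromNodes(res$attn, lastNLayers)
  out
}

# Encoder stack given an assembled-token node (position embedding included).
encoderTape <- function(config, pn, xNode, wantAttention = FALSE) {
  x <- adAdd(xNode, pn[["pos"]])
  dk <- headDim(config)
  attn <- if (wantAttention) vector("list", config@nLayers)
  for (l in seq_len(config@nLayers)) {
    heads <- vector("list", config@nHeads)
    if (wantAttention) attn[[l]] <- vector("list", config@nHeads)
    for (hh in seq_len(config@nHeads)) {
      Q <- adMatmul(x, pn[[sprintf("L%d_h%d_Wq", l, hh)]])
      K <- adMatmul(x, pn[[sprintf("L%d_h%d_Wk", l, hh)]])
      V <- adMatmul(x, pn[[sprintf("L%d_h%d_Wv", l, hh)]])
      A <- adSoftmaxRows(adScale(adMatmul(Q, K, transposeB = TRUE), 1 / sqrt(dk)))
      if (wantAttention) attn[[l]][[hh]] <- A
      heads[[hh]] <- adMatmul(A, V)
    }
    mh <- heads[[1]]
    for (hh in seq_len(config@nHeads)[-1]) mh <- adCbind(mh, heads[[hh]])
    proj <- adAdd(adMatmul(mh, pn[[sprintf("L%d_Wo", l)]]), pn[[sprintf("L%d_bo", l)]])
    x <- adLayerNormRows(adAdd(x, proj),
                         pn[[sprintf("L%d_ln1_g", l)]], pn[[sprintf("L%d_ln1_b", l)]])
    ff <- adAdd(adMatmul(x, pn[[sprintf("L%d_ffn_W1", l)]]), pn[[sprintf("L%d_ffn_b1", l)]])
    ff <- adGELU(ff)
    ff <- adAdd(adMatmul(ff, pn[[sprintf("L%d_ffn_W2", l)]]), pn[[sprintf("L%d_ffn_b2", l)]])
    x <- adLayerNormRows(adAdd(x, ff),
                         pn[[sprintf("L%d_ln2_g", l)]], pn[[sprintf("L%d_ln2_b", l)]])
  }
  list(x = x, attn = attn)
}

#' Write a model checkpoint
#'
#' Single JSON text file holding the config and every named weight tensor
#' at full double precision; round-trips through
#' \code{\link{readCheckpoint}}.
#'
#' @param model an \code{EpiModel}.
#' @param path output path.
#' @export
writeCheckpoint <- function(model, path) {
  cfg <- model@config
  obj <- list(
    format = "epicontext-checkpoint", version = 1L,
    config = list(inputLength = cfg@inputLength, binSize = cfg@binSize,
                  seqChannels = cfg@seqChannels, nTF = cfg@nTF,
                  nTFPadded = cfg@nTFPadded, nHeads = cfg@nHeads,
                  nLayers = cfg@nLayers, nSignals = cfg@nSignals,
                  headType = cfg@headType, poolFactors = cfg@poolFactors,
                  convChannels = cfg@convChannels, convKernel = cfg@convKernel,
                  ffnMult = cfg@ffnMult),
    params = model@params)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path file written by \code{\link{writeCheckpoint}}.
#' @return An \code{EpiModel}.
#' @export
readCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- obj$config
  cfg <- new("ModelConfig", inputLength = cf$inputLength, binSize = cf$binSize,
             seqChannels = as.integer(cf$seqChannels), nTF = as.integer(cf$nTF),
             nTFPadded = as.integer(cf$nTFPadded), nHeads = as.integer(cf$nHeads),
             nLayers = as.integer(cf$nLayers), nSignals = as.integer(cf$nSignals),
             headType = cf$headType, poolFactors = as.numeric(cf$poolFactors),
             convChannels = as.integer(cf$convChannels),
             convKernel = as.integer(cf$convKernel), ffnMult = cf$ffnMult)
  params <- lapply(obj$params, function(p) if (is.list(p)) do.call(rbind, p) else p)
  new("EpiModel", config = cfg, params = params)
}

#' Full forward pass: sequence + TF features to per-token signals
#'
#' @param model an \code{EpiModel}.
#' @param onehot L x 4 one-hot matrix of the input window.
#' @param tfInput tokens x nTFPadded combined TF features for one context
#'   (\code{\link{combineTF}}).
#' @param returnAttention capture attention matrices.
#' @param lastNLayers trailing layers for the head-averaged attention.
#' @return list with \code{pred} (tokens x K), \code{hidden}
#'   (tokens x dModel) and optionally \code{attention}
#'   (\code{\linkS4class{AttentionSummary}}).
#' @export
predictSignals <- function(model, onehot, tfInput, returnAttention = FALSE,
                           lastNLayers = 1L) {
  tape <- adTape()
  pn <- paramLeaves(tape, model@params)
  res <- forwardTape(model@config, pn, onehot, tfInput, tape,
                     wantAttention = returnAttention)
  out <- list(pred = adVal(res$pred), hidden = adVal(res$hidden))
  if (returnAttention)
    out$attention <- attentionSummaryFromNodes(res$attn, lastNLayers)
  out
}
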