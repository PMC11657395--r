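# Central S4 containers. Coordinates are 0-based half-open (BED convention)
# at the genome level; bin/token indices are 1-based inside R.

#' Default epigenomic signal panel
#'
#' The eight signals the multi-task head predicts by default: chromatin
#' accessibility, CTCF occupancy, and six histone marks.
#' @export
DEFAULT_SIGNALS <- c("DNase", "CTCF", "H3K27ac", "H3K4me3",
                     "H3K36me3", "H3K27me3", "H3K9me3", "H3K4me1")

#' BinnedRegion: a genomic window partitioned into fixed-width bins
#'
#' The coordinate frame shared by every downstream object: a single window
#' \code{[start, end)} on one chromosome, cut into \code{nBins} bins of
#' \code{binSize} bp. Bin \code{j} (1-based) spans
#' \code{[start + (j-1)*binSize, start + j*binSize)}.
#'
#' @slot chrom chromosome name.
#' @slot start,end 0-based half-open window coordinates.
#' @slot binSize bin width in bp.
#' @slot nBins number of bins, \code{(end - start)/binSize}.
#' @export
setClass("BinnedRegion",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 binSize = "numeric", nBins = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@end <= object@start)
      msg <- c(msg, "end must exceed start")
    if (object@binSize <= 0)
      msg <- c(msg, "binSize must be positive")
    span <- object@end - object@start
    if (span %% object@binSize != 0)
      msg <- c(msg, sprintf("span %d not divisible by binSize %d (remainder %d)",
                            span, object@binSize, span %% object@binSize))
    else if (object@nBins != span %/% object@binSize)
      msg <- c(msg, "nBins inconsistent with span/binSize")
    if (length(msg)) msg else TRUE
  })

#' CountMatrix: raw read counts with per-context library depths
#'
#' Houses the raw counts \eqn{n_{lk}} for locus \eqn{l} in context \eqn{k}
#' and the total pooled read counts \eqn{N_k} used for sequencing-depth
#' normalization. Depths are library totals, not window sums.
#'
#' @slot counts loci x contexts non-negative matrix.
#' @slot depths per-context positive library totals.
#' @export
setClass("CountMatrix",
  representation(counts = "matrix", depths = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@depths) != ncol(object@counts))
      msg <- c(msg, "one depth per context column required")
    if (any(object@depths <= 0))
      msg <- c(msg, "all depths must be positive")
    if (any(object@counts < 0))
      msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' SignalTensor: processed signals with an availability mask
#'
#' A contexts x bins x signals array of processed (depth-normalized,
#' log1p-transformed) signal levels together with a contexts x signals
#' logical mask saying which (context, signal) tracks were measured.
#' Masked-out cells never enter losses or metrics.
#'
#' @slot values contexts x bins x signals numeric array.
#' @slot mask contexts x signals logical availability matrix.
#' @slot signalNames ordered signal names (see \code{\link{DEFAULT_SIGNALS}}).
#' @slot contexts cellular context identifiers.
#' @slot region the \code{BinnedRegion} the bins refer to.
#' @export
setClass("SignalTensor",
  representation(values = "array", mask = "matrix", signalNames = "character",
                 contexts = "character", region = "BinnedRegion"),
  validity = function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 3)
      msg <- c(msg, "values must be a 3-d array (contexts x bins x signals)")
    else {
      if (d[1] != length(object@contexts)) msg <- c(msg, "context dimension mismatch")
      if (d[2] != object@region@nBins) msg <- c(msg, "bin dimension mismatch")
      if (d[3] != length(object@signalNames)) msg <- c(msg, "signal dimension mismatch")
      if (!all(dim(object@mask) == d[c(1, 3)])) msg <- c(msg, "mask must be contexts x signals")
      for (k in seq_len(d[3])) for (c in seq_len(d[1])) if (isTRUE(object@mask[c, k])) {
        v <- object@values[c, , k]
        if (!all(is.finite(v))) { msg <- c(msg, "non-finite values in an available track"); break }
        if (any(v < 0)) { msg <- c(msg, "processed values must be >= 0"); break }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' PWMSet: a set of position weight matrices
#'
#' Log-odds position weight matrices (width x 4 over A,C,G,T), one per TF.
#'
#' @slot pwms named list of width x 4 numeric matrices.
#' @export
setClass("PWMSet",
  representation(pwms = "list"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@pwms)) || anyDuplicated(names(object@pwms)))
      msg <- c(msg, "pwms must have unique names")
    for (m in object@pwms) {
      if (!is.matrix(m) || ncol(m) != 4 || nrow(m) < 1) { msg <- c(msg, "each PWM must be a width x 4 matrix"); break }
      if (!all(is.finite(m))) { msg <- c(msg, "PWM entries must be finite"); break }
    }
    if (length(msg)) msg else TRUE
  })

#' TFFeatureBlock: per-bin motif scores and per-context expression
#'
#' The context token factors: a bins x nTF matrix of maximal PWM match
#' scores (floored at 0) and a contexts x nTF matrix of quantile-normalized
#' log1p TPM. The model input is their element-wise (broadcast) product,
#' zero-padded to \code{nTFPadded} columns.
#'
#' @slot motifScores bins x nTF non-negative matrix.
#' @slot expression contexts x nTF matrix.
#' @slot nTFPadded model TF width (>= nTF); padded columns are exactly zero.
#' @export
setClass("TFFeatureBlock",
  representation(motifScores = "matrix", expression = "matrix",
                 nTFPadded = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@motifScores) != ncol(object@expression))
      msg <- c(msg, "motifScores and expression must agree on nTF")
    if (any(object@motifScores < 0))
      msg <- c(msg, "motif scores must be >= 0")
    if (object@nTFPadded < ncol(object@motifScores))
      msg <- c(msg, "nTFPadded must be >= nTF")
    if (length(msg)) msg else TRUE
  })

#' ContactMatrix: bin-level chromatin-contact aggregate
#'
#' Loop scores aggregated symmetrically onto bin pairs (\code{H}) and the
#' row-normalized form (\code{Hnorm}; rows with nonzero sum sum to 1,
#' all-zero rows stay zero and are flagged in \code{validRows}).
#'
#' @slot H tokens x tokens symmetric non-negative matrix.
#' @slot Hnorm row-normalized form of \code{H}.
#' @slot validRows logical; TRUE where the row of \code{H} is nonzero.
#' @slot resolution source loop resolution in bp.
#' @export
setClass("ContactMatrix",
  representation(H = "matrix", Hnorm = "matrix", validRows = "logical",
                 resolution = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@H) != ncol(object@H)) msg <- c(msg, "H must be square")
    if (any(object@H < 0)) msg <- c(msg, "H must be non-negative")
    if (max(abs(object@H - t(object@H))) > 1e-8) msg <- c(msg, "H must be symmetric")
    rs <- rowSums(object@Hnorm)
    if (any(abs(rs[object@validRows] - 1) > 1e-8)) msg <- c(msg, "valid Hnorm rows must sum to 1")
    if (any(rs[!object@validRows] != 0)) msg <- c(msg, "invalid Hnorm rows must be zero")
    if (length(msg)) msg else TRUE
  })

#' AttentionSummary: captured self-attention matrices
#'
#' Per-layer, per-head row-stochastic attention matrices, their average over
#' all layers and heads, and the head average over the last layer(s) used by
#' the contact-guidance loss.
#'
#' @slot attention list (layers) of lists (heads) of tokens x tokens matrices.
#' @slot meanAttention average over all layers and heads.
#' @slot lastAttention head average over the last \code{lastNLayers} layer(s).
#' @slot lastNLayers how many trailing layers entered \code{lastAttention}.
#' @export
setClass("AttentionSummary",
  representation(attention = "list", meanAttention = "matrix",
                 lastAttention = "matrix", lastNLayers = "integer"))

#' ModelConfig: architecture hyper-parameters
#'
#' Scale-configurable description of the network. The published-scale
#' profile is L = 128000, binSize = 128, seqChannels = 256, nTFPadded = 712
#' (711 TFs plus padding), dModel = 968, nHeads = 8 (per-head width 121),
#' nLayers 12 or 16, nSignals = 8.
#'
#' @slot inputLength input sequence length L in bp.
#' @slot binSize bin (token) width N in bp; tokens = L/N.
#' @slot seqChannels C, sequence-embedding channels out of the conv stack.
#' @slot nTF number of TFs before padding.
#' @slot nTFPadded TF feature width after zero padding.
#' @slot nHeads attention heads; dModel must divide evenly.
#' @slot nLayers transformer encoder layers.
#' @slot nSignals output tracks K.
#' @slot headType "regression" (linear) or "classification" (linear+sigmoid).
#' @slot poolFactors five max-pool factors whose product equals binSize.
#' @slot convChannels output channels of the five conv blocks (last = C).
#' @slot convKernel conv kernel width (same for all blocks).
#' @slot ffnMult feed-forward hidden width as a multiple of dModel.
#' @export
setClass("ModelConfig",
  representation(inputLength = "numeric", binSize = "numeric",
                 seqChannels = "integer", nTF = "integer", nTFPadded = "integer",
                 nHeads = "integer", nLayers = "integer", nSignals = "integer",
                 headType = "character", poolFactors = "numeric",
                 convChannels = "integer", convKernel = "integer",
                 ffnMult = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- object@seqChannels + object@nTFPadded
    if (d %% object@nHeads != 0)
      msg <- c(msg, sprintf("dModel %d not divisible by nHeads %d", d, object@nHeads))
    if (prod(object@poolFactors) != object@binSize)
      msg <- c(msg, "product of poolFactors must equal binSize")
    if (object@inputLength %% object@binSize != 0)
      msg <- c(msg, "inputLength must be a multiple of binSize")
    if (length(object@poolFactors) != length(object@convChannels))
      msg <- c(msg, "one pool factor per conv block required")
    if (utils::tail(object@convChannels, 1) != object@seqChannels)
      msg <- c(msg, "last conv block must output seqChannels")
    if (!object@headType %in% c("regression", "classification"))
      msg <- c(msg, "headType must be 'regression' or 'classification'")
    if (length(msg)) msg else TRUE
  })

#' EpiModel: a parameterized network
#'
#' @slot config the \code{ModelConfig}.
#' @slot params named list of weight matrices/vectors.
#' @export
setClass("EpiModel",
  representation(config = "ModelConfig", params = "list"))

#' TrainConfig: optimizer and loss settings
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 5e-5, minibatch size 10, contact-guidance weight alpha = 2 when 3D data
#' are supplied (alpha = 0 disables guidance exactly).
#'
#' @slot learningRate Adam step size.
#' @slot batchSize minibatch size (training instances = context x region pairs).
#' @slot alpha weight of the contact-guidance (cosine-similarity) loss.
#' @slot steps number of optimization steps.
#' @slot seed RNG seed (mandatory; training is deterministic given it).
#' @slot lastNLayers how many trailing layers' head-averaged attention feed
#'   the contact-guidance loss (default 1).
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 alpha = "numeric", steps = "integer", seed = "integer",
                 lastNLayers = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
    if (length(msg)) msg else TRUE
  })
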