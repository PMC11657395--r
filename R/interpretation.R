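# Attribution and scoring machinery: gradient importance scores for TF ->
# target ranking, attention-based element-gene scores, and log-ratio
# variant-effect scores.

#' Gradient importance scores (GIS) for all TFs and signals
#'
#' For each TF t, let \eqn{\zeta_t} be the set of bins with a positive motif
#' score ("bins that have binding"). The GIS of TF t for signal k is the
#' mean over \eqn{l \in \zeta_t} of the absolute gradient of the predicted
#' signal \eqn{\hat y_{lk}} with respect to the TF's input entry. Two
#' differentiation targets are supported, matching the two published uses:
#' \describe{
#'   \item{\code{"product"}}{the combined motif-times-expression entry of
#'     the output bin itself, \eqn{|\partial\hat y_{lk}/\partial x_{lt}|}.}
#'   \item{\code{"expression"}}{the scalar expression entry, whose gradient
#'     chains through every bin:
#'     \eqn{|\sum_b m_{bt}\,\partial\hat y_{lk}/\partial x_{bt}|}.}
#' }
#' A TF with empty \eqn{\zeta} gets GIS 0 and is flagged.
#'
#' @param model an \code{EpiModel}.
#' @param onehot L x 4 one-hot window (TSS-centered at the published scale).
#' @param motifScoreMat bins x nTF motif max-score matrix for the window.
#' @param expressionRow length-nTF expression vector of the context.
#' @param mode differentiation target, \code{"product"} (default) or
#'   \code{"expression"}.
#' @return list: \code{gis} (nTF x K matrix), \code{zeta} (list of bin
#'   indices per TF), \code{emptyZeta} (logical flags).
#' @export
gisTable <- function(model, onehot, motifScoreMat, expressionRow,
                     mode = c("product", "expression")) {
  mode <- match.arg(mode)
  cfg <- model@config
  nTF <- ncol(motifScoreMat)
  K <- cfg@nSignals
  tfInput <- combineTF(motifScoreMat, expressionRow, cfg@nTFPadded)
  zeta <- lapply(seq_len(nTF), function(t) which(motifScoreMat[, t] > 0))
  names(zeta) <- colnames(motifScoreMat)
  lset <- sort(unique(unlist(zeta)))
  gis <- matrix(0, nTF, K,
                dimnames = list(colnames(motifScoreMat),
                                paste0("signal", seq_len(K))))
  if (length(lset)) {
    tape <- adTape()
    pn <- paramLeaves(tape, model@params)
    tfNode <- adLeaf(tape, tfInput)
    fw <- forwardTape(cfg, pn, onehot, tfNode, tape)
    pv <- adVal(fw$pred)
    # one reverse pass per (output bin, signal); each yields the gradient of
    # that scalar prediction w.r.t. the whole TF input block at once
    gradAbs <- array(0, c(length(lset), nTF, K))
    for (li in seq_along(lset)) for (k in seq_len(K)) {
      seed <- matrix(0, nrow(pv), ncol(pv))
      seed[lset[li], k] <- 1
      adBackward(fw$pred, seed)
      G <- tfNode$grad[, seq_len(nTF), drop = FALSE]
      gradAbs[li, , k] <- switch(mode,
        product = abs(G[lset[li], ]),
        expression = abs(colSums(G * motifScoreMat)))
    }
    for (t in seq_len(nTF)) {
      z <- zeta[[t]]
      if (!length(z)) next
      rows <- match(z, lset)
      gis[t, ] <- colMeans(gradAbs[rows, t, , drop = FALSE], dims = 1)
    }
  }
  list(gis = gis, zeta = zeta, emptyZeta = lengths(zeta) == 0)
}

#' Integrated gradient importance score (IGIS)
#'
#' Ranks TFs within each signal by descending GIS (rank 1 = largest, ties
#' get the average rank) and averages the ranks over the K signals.
#' A TF ranked first everywhere scores exactly 1.
#'
#' @param gisMatrix nTF x K GIS matrix.
#' @return length-nTF vector of mean ranks (smaller = more important).
#' @export
igis <- function(gisMatrix) {
  ranks <- apply(gisMatrix, 2, function(col) rank(-col, ties.method = "average"))
  out <- rowMeans(ranks)
  names(out) <- rownames(gisMatrix)
  out
}

#' Attention score for an element-gene pair
#'
#' Uses the attention matrix averaged over all layers and heads. In
#' \code{"column"} mode (default) the score is the total attention the
#' element's token receives from every query token (column sum); in
#' \code{"direct"} mode it is the single entry from the element's bin to the
#' TSS bin. Pairs farther apart than half the window (64 kb at the
#' published scale) are rejected.
#'
#' @param att \code{AttentionSummary} or tokens x tokens matrix (the
#'   all-layer, all-head average).
#' @param elementBin,tssBin 1-based token indices.
#' @param binSize bin width in bp (for the distance filter).
#' @param maxDistance maximum pair distance in bp; default half of the
#'   token span.
#' @param mode \code{"column"} or \code{"direct"}.
#' @return scalar attention score.
#' @export
attentionPairScore <- function(att, elementBin, tssBin, binSize = 128,
                               maxDistance = NULL,
                               mode = c("column", "direct")) {
  mode <- match.arg(mode)
  A <- if (is(att, "AttentionSummary")) meanAttention(att) else att
  Tn <- nrow(A)
  if (elementBin < 1 || elementBin > Tn || tssBin < 1 || tssBin > Tn)
    stop("bin index outside the token range")
  if (is.null(maxDistance)) maxDistance <- Tn * binSize / 2
  dist <- abs(elementBin - tssBin) * binSize
  if (dist > maxDistance)
    stop(sprintf("pair %d bp apart exceeds the %d bp window limit",
                 dist, as.integer(maxDistance)))
  switch(mode,
         column = sum(A[, elementBin]),
         direct = A[elementBin, tssBin])
}

#' Per-signal log-ratio variant-effect scores
#'
#' Runs a forward pass on the reference and alternative windows and returns
#' \eqn{\log((\hat y_{alt}+\epsilon)/(\hat y_{ref}+\epsilon))} per signal at
#' the variant's bin (natural log; outputs are clamped at 0 then floored at
#' \code{eps} so the ratio is finite). Signed: the direction of change is
#' kept. SNVs only — the two windows must have equal length and differ at
#' the variant position alone.
#'
#' @param model an \code{EpiModel}.
#' @param refOnehot,altOnehot L x 4 one-hot matrices.
#' @param tfInput tokens x nTFPadded combined TF features of the context,
#'   computed on the reference allele.
#' @param variantBin 1-based bin (token) index of the variant.
#' @param eps ratio floor.
#' @param tfInputAlt TF features recomputed on the alternative allele (the
#'   variant can create or destroy motif matches); defaults to
#'   \code{tfInput}, i.e. a sequence-only effect.
#' @return length-K signed vector.
#' @export
losSignal <- function(model, refOnehot, altOnehot, tfInput, variantBin,
                      eps = 1e-6, tfInputAlt = tfInput) {
  if (nrow(refOnehot) != nrow(altOnehot))
    stop("ref/alt window length mismatch (indels are not supported)")
  diffRows <- which(rowSums(refOnehot != altOnehot) > 0)
  if (length(diffRows) > 1)
    stop("ref and alt must differ at the variant locus only")
  Tn <- nTokens(model@config)
  ctr <- ceiling(Tn / 2)
  if (abs(variantBin - ctr) > 1)
    warning("variant is not centered in the window")
  ref <- predictSignals(model, refOnehot, tfInput)$pred[variantBin, ]
  alt <- predictSignals(model, altOnehot, tfInputAlt)$pred[variantBin, ]
  log((pmax(alt, 0) + eps) / (pmax(ref, 0) + eps))
}

#' Attention log-ratio variant-effect score
#'
#' Sums, over the 11 bins at offsets -5..+5 around the variant, the
#' absolute natural-log ratio of per-bin attention mass between the
#' alternative and reference windows. Attention mass of a bin is the row
#' sum of the layer/head-averaged attention (\code{mode = "row"}), its
#' column sum, or their sum. Offsets falling outside the token range are
#' truncated with a warning.
#'
#' @param attRef,attAlt \code{AttentionSummary} or averaged matrices for
#'   the reference and alternative windows.
#' @param variantBin 1-based bin index of the variant.
#' @param halfWidth neighborhood half-width in bins (published formula: 5).
#' @param eps mass floor.
#' @param mode \code{"row"}, \code{"column"} or \code{"both"}.
#' @return scalar score >= 0.
#' @export
losAttention <- function(attRef, attAlt, variantBin, halfWidth = 5L,
                         eps = 1e-6, mode = c("row", "column", "both")) {
  mode <- match.arg(mode)
  Ar <- if (is(attRef, "AttentionSummary")) meanAttention(attRef) else attRef
  Aa <- if (is(attAlt, "AttentionSummary")) meanAttention(attAlt) else attAlt
  mass <- function(A) switch(mode, row = rowSums(A), column = colSums(A),
                             both = rowSums(A) + colSums(A))
  mr <- mass(Ar); ma <- mass(Aa)
  offs <- (variantBin - halfWidth):(variantBin + halfWidth)
  inside <- offs >= 1 & offs <= length(mr)
  if (!all(inside)) {
    warning("attention neighborhood truncated at the window edge")
    offs <- offs[inside]
  }
  sum(abs(log((ma[offs] + eps) / (mr[offs] + eps))))
}

#' Per-variant feature vector across contexts
#'
#' For each context: the K per-signal log-ratio scores followed by the
#' attention log-ratio score, concatenated in the given context order —
#' 9 features per context at the published K = 8, hence 252 features for
#' 28 contexts.
#'
#' @param model an \code{EpiModel}.
#' @param refOnehot,altOnehot the two windows.
#' @param tfInputs named list (one tokens x nTFPadded matrix per context),
#'   computed on the reference allele.
#' @param variantBin 1-based bin index of the variant.
#' @param eps ratio floor.
#' @param tfInputsAlt TF features recomputed on the alternative allele;
#'   defaults to \code{tfInputs}.
#' @return numeric vector of length \code{(K + 1) * length(tfInputs)},
#'   named \code{<context>.<signal>} / \code{<context>.attention}.
#' @export
variantFeatures <- function(model, refOnehot, altOnehot, tfInputs,
                            variantBin, eps = 1e-6, tfInputsAlt = tfInputs) {
  if (!length(tfInputs)) stop("at least one context is required")
  K <- model@config@nSignals
  out <- numeric(0)
  for (ci in seq_along(tfInputs)) {
    tf <- tfInputs[[ci]]
    ref <- predictSignals(model, refOnehot, tf, returnAttention = TRUE)
    alt <- predictSignals(model, altOnehot, tfInputsAlt[[ci]],
                          returnAttention = TRUE)
    los <- log((pmax(alt$pred[variantBin, ], 0) + eps) /
               (pmax(ref$pred[variantBin, ], 0) + eps))
    la <- losAttention(ref$attention, alt$attention, variantBin, eps = eps)
    nm <- names(tfInputs)[ci]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("context", ci)
    block <- c(los, la)
    names(block) <- paste0(nm, ".", c(paste0("signal", seq_len(K)), "attention"))
    out <- c(out, block)
  }
  out
}

#' Percentile rank of a score within background scores
#'
#' Fraction of background scores strictly exceeding the score, with a
#' midrank correction for ties: 0 means the score beats the whole
#' background (best possible rank), and exchangeable score/background draws
#' average 0.5 under the null.
#'
#' @param score a single score.
#' @param background nonempty numeric vector of background scores (for SNP
#'   prioritization: variants in the surrounding risk window).
#' @return value in [0, 1].
#' @export
percentileRank <- function(score, background) {
  if (!length(background)) stop("background must be nonempty")
  (sum(background > score) + 0.5 * sum(background == score)) / length(background)
}

#' Overlapping k-mer count features
#'
#' Counts all overlapping k-mers over the A/C/G/T alphabet (4^k features,
#' 1024 for the default k = 5); k-mers containing ambiguous bases are
#' dropped. A sequence shorter than k yields a zero vector with a warning.
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param k k-mer length.
#' @return named integer vector of length 4^k.
#' @export
kmerFeatures <- function(seq, k = 5L) {
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  if (length(s) < k) {
    warning("sequence shorter than k; returning zero vector")
    return(stats::setNames(integer(4^k),
                           Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)))
  }
  Biostrings::oligonucleotideFrequency(s, width = k)
}
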