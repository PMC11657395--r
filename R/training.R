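# Losses and optimization: masked multi-task MSE over available signals,
# contact-guided attention (cosine-similarity loss against row-normalized
# loop aggregates), Adam, and the frozen-backbone pair-classification head.

#' Build a TrainConfig
#'
#' Defaults follow the published recipe: Adam, learning rate 5e-5, batch
#' size 10, contact-guidance weight alpha = 2.
#'
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param alpha contact-guidance loss weight (0 disables guidance exactly).
#' @param steps optimization steps.
#' @param seed mandatory RNG seed.
#' @param lastNLayers trailing layers whose head-averaged attention feeds
#'   the guidance loss.
#' @return A \code{\linkS4class{TrainConfig}}.
#' @export
trainConfig <- function(learningRate = 5e-5, batchSize = 10L, alpha = 2,
                        steps = 500L, seed, lastNLayers = 1L) {
  if (missing(seed)) stop("a seed is mandatory for training")
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), alpha = alpha,
      steps = as.integer(steps), seed = as.integer(seed),
      lastNLayers = as.integer(lastNLayers))
}

#' Masked multi-task mean squared error
#'
#' For one instance: the mean over bins of the mean squared error over the
#' available signals \eqn{B_i} only,
#' \eqn{(1/J)\sum_j (1/|B_i|)\sum_{k\in B_i}(y_{jk}-\hat y_{jk})^2}.
#' An instance with no available signal contributes 0.
#'
#' @param pred,target bins x K matrices.
#' @param avail logical K-vector of available signals.
#' @return scalar loss.
#' @export
maskedMSE <- function(pred, target, avail) {
  if (!all(dim(pred) == dim(target))) stop("pred/target shape mismatch")
  nb <- sum(avail)
  if (nb == 0) return(0)
  if (any(!is.finite(target[, avail, drop = FALSE])))
    stop("NaN in available target cells")
  D <- (pred - target)[, avail, drop = FALSE]
  sum(D * D) / (nrow(pred) * nb)
}

#' Parse BEDPE loop records
#'
#' Minimal BEDPE reader: six coordinate columns, then name, score and
#' further numeric columns; the q-value column is selected by index or
#' name. Malformed lines are rejected with their line number.
#'
#' @param path BEDPE file path.
#' @param qCol q-value column (1-based index, or name when a header line
#'   starting with "#" is present). Default: column 9.
#' @param scoreCol normalized-count column. Default: column 8.
#' @return data.frame with chrom1,start1,end1,chrom2,start2,end2,score,qvalue.
#' @export
readLoops <- function(path, scoreCol = 8L, qCol = 9L) {
  lines <- readLines(path)
  header <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    header <- strsplit(sub("^#\\s*", "", lines[1]), "\t")[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  resolveCol <- function(col) {
    if (is.character(col)) {
      if (is.null(header)) stop("named q/score column requires a # header line")
      i <- match(col, header)
      if (is.na(i)) stop("no BEDPE column named '", col, "'")
      i
    } else as.integer(col)
  }
  si <- resolveCol(scoreCol); qi <- resolveCol(qCol)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < max(6L, si, qi))
      stop(sprintf("malformed BEDPE line %d: %d fields", i, length(f)))
    co <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6, si, qi)]))
    if (anyNA(co))
      stop(sprintf("malformed BEDPE line %d: non-numeric coordinate/score", i))
    out[[i]] <- data.frame(chrom1 = f[1], start1 = co[1], end1 = co[2],
                           chrom2 = f[4], start2 = co[3], end2 = co[4],
                           score = co[5], qvalue = co[6])
  }
  do.call(rbind, out)
}

#' Aggregate loops into a bin-level contact matrix
#'
#' Loops are filtered at a stringent q-value threshold (default 0.001), then
#' each surviving loop's normalized count is added symmetrically to every
#' (bin_a, bin_b) pair its two anchors overlap. Rows of the aggregate H are
#' normalized to sum to 1 where nonzero, giving \eqn{\tilde H}; all-zero
#' rows stay zero and are flagged invalid.
#'
#' @param loops data.frame from \code{\link{readLoops}} (or equivalent).
#' @param region the \code{BinnedRegion} of the model window.
#' @param qThreshold keep loops with \code{qvalue <= qThreshold}.
#' @return A \code{\linkS4class{ContactMatrix}}.
#' @export
buildContactMatrix <- function(loops, region, qThreshold = 0.001) {
  nb <- region@nBins
  H <- matrix(0, nb, nb)
  if (!is.null(loops) && nrow(loops)) {
    keep <- loops$qvalue <= qThreshold & loops$chrom1 == region@chrom &
      loops$chrom2 == region@chrom
    loops <- loops[keep, , drop = FALSE]
    for (i in seq_len(nrow(loops))) {
      binsA <- overlappedBins(region, loops$start1[i], loops$end1[i])
      binsB <- overlappedBins(region, loops$start2[i], loops$end2[i])
      if (!length(binsA) || !length(binsB)) next
      for (a in binsA) for (b in binsB) {
        H[a, b] <- H[a, b] + loops$score[i]
        H[b, a] <- H[b, a] + loops$score[i]
      }
    }
  }
  rs <- rowSums(H)
  valid <- rs > 0
  Hn <- H
  Hn[valid, ] <- H[valid, , drop = FALSE] / rs[valid]
  new("ContactMatrix", H = H, Hnorm = Hn, validRows = valid,
      resolution = region@binSize)
}

# 1-based indices of bins overlapped by [start, end) clipped to the region.
overlappedBins <- function(region, start, end) {
  s <- max(start, region@start)
  e <- min(end, region@end)
  if (e <= s) return(integer(0))
  first <- (s - region@start) %/% region@binSize + 1
  last <- (e - 1 - region@start) %/% region@binSize + 1
  as.integer(first:last)
}

#' @describeIn buildContactMatrix raw symmetric aggregate H.
#' @param x a \code{ContactMatrix}.
#' @export
setMethod("contactCounts", "ContactMatrix", function(x) x@H)

#' @describeIn buildContactMatrix row-normalized form \eqn{\tilde H}.
#' @export
setMethod("normalizedContacts", "ContactMatrix", function(x) x@Hnorm)

#' @describeIn buildContactMatrix logical vector of rows with any contact.
#' @export
setMethod("validContactRows", "ContactMatrix", function(x) x@validRows)

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %d x %d bins, %d rows with contacts\n",
              nrow(object@H), ncol(object@H), sum(object@validRows)))
})

#' Contact-guidance (cosine-similarity) loss
#'
#' \code{1 - mean} over valid rows (rows of \eqn{\tilde H} with contacts) of
#' the cosine between the head-averaged last-layer attention row and the
#' \eqn{\tilde H} row. 0 means every valid attention row is positively
#' proportional to its contact row; the range is [0, 2]. If no row is valid
#' the loss is 0 with a warning.
#'
#' @param att tokens x tokens attention matrix (head-averaged, last
#'   layer(s)), or an \code{\linkS4class{AttentionSummary}}.
#' @param contacts a \code{\linkS4class{ContactMatrix}} (or a row-normalized
#'   matrix, in which case \code{validRows} is derived from nonzero rows).
#' @return scalar loss.
#' @export
contactGuidanceLoss <- function(att, contacts) {
  A <- if (is(att, "AttentionSummary")) lastLayerAttention(att) else att
  if (is(contacts, "ContactMatrix")) {
    Hn <- contacts@Hnorm; valid <- contacts@validRows
  } else {
    Hn <- contacts; valid <- rowSums(Hn) > 0
  }
  if (!all(dim(A) == dim(Hn))) stop("attention/contact shape mismatch")
  if (!any(valid)) {
    warning("no contact rows; guidance loss is 0")
    return(0)
  }
  rows <- which(valid)
  a <- A[rows, , drop = FALSE]; h <- Hn[rows, , drop = FALSE]
  cosr <- rowSums(a * h) /
    (pmax(sqrt(rowSums(a * a)), 1e-12) * sqrt(rowSums(h * h)))
  1 - mean(cosr)
}

#' Total training loss
#'
#' \code{maskedMSE + alpha * contactGuidanceLoss}; \code{alpha = 0} reduces
#' exactly to the masked MSE.
#'
#' @inheritParams maskedMSE
#' @param att attention matrix or \code{AttentionSummary}.
#' @param contacts a \code{ContactMatrix} (ignored when \code{alpha = 0}).
#' @param alpha guidance weight (published value 2).
#' @export
totalLoss <- function(pred, target, avail, att = NULL, contacts = NULL,
                      alpha = 0) {
  l <- maskedMSE(pred, target, avail)
  if (alpha > 0) {
    if (is.null(att) || is.null(contacts))
      stop("alpha > 0 requires attention and contacts")
    l <- l + alpha * contactGuidanceLoss(att, contacts)
  }
  l
}

#' A training instance
#'
#' Bundles one (cellular context, genomic region) pair: the one-hot window,
#' the combined TF input for the context, the target signals, the signal
#' availability, and optionally the region's contact matrix.
#'
#' @param onehot L x 4 one-hot matrix.
#' @param tfInput tokens x nTFPadded combined TF features.
#' @param target tokens x K signal matrix.
#' @param avail logical K availability vector.
#' @param contacts optional \code{ContactMatrix}.
#' @param context,regionId optional identifiers.
#' @export
trainInstance <- function(onehot, tfInput, target, avail, contacts = NULL,
                          context = NA_character_, regionId = NA_character_) {
  list(onehot = onehot, tfInput = tfInput, target = target, avail = avail,
       contacts = contacts, context = context, regionId = regionId)
}

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a model with masked multi-task loss and optional contact guidance
#'
#' Minibatch Adam over (context, region) instances. Each step draws a batch,
#' builds one autodiff tape over all its instances, averages
#' \code{maskedMSE + alpha * CSL}, backpropagates and updates. Training is
#' deterministic given the seed. A non-finite loss aborts, returning the
#' last finite-loss parameters.
#'
#' @param model an \code{EpiModel}.
#' @param instances nonempty list of \code{\link{trainInstance}} objects.
#' @param config a \code{\linkS4class{TrainConfig}}.
#' @param verbose print the loss every 50 steps.
#' @return list with \code{model} (trained) and \code{history} (data.frame
#'   of step, loss, mse, csl).
#' @export
trainModel <- function(model, instances, config, verbose = FALSE) {
  if (!length(instances)) stop("empty training dataset")
  stopifnot(validObject(config))
  set.seed(config@seed)
  params <- model@params
  cfg <- model@config
  opt <- adamInit(params)
  hist <- data.frame(step = integer(), loss = numeric(), mse = numeric(),
                     csl = numeric())
  lastGood <- params
  for (step in seq_len(config@steps)) {
    idx <- sample.int(length(instances), min(config@batchSize, length(instances)))
    tape <- adTape()
    pn <- paramLeaves(tape, params)
    lossNodes <- vector("list", length(idx))
    mseAcc <- 0; cslAcc <- 0
    for (b in seq_along(idx)) {
      inst <- instances[[idx[b]]]
      wantA <- config@alpha > 0 && !is.null(inst$contacts)
      fw <- forwardTape(cfg, pn, inst$onehot, inst$tfInput, tape,
                        wantAttention = wantA)
      ln <- adMaskedMSE(fw$pred, inst$target, inst$avail)
      mseAcc <- mseAcc + adVal(ln)
      if (wantA) {
        li <- seq(cfg@nLayers - config@lastNLayers + 1L, cfg@nLayers)
        lastA <- unlist(fw$attn[li], recursive = FALSE)
        aAvg <- adMeanOf(lastA)
        cn <- adCosineRowsLoss(aAvg, inst$contacts@Hnorm,
                               inst$contacts@validRows)
        cslAcc <- cslAcc + adVal(cn)
        ln <- adAdd(ln, adScale(cn, config@alpha))
      }
      lossNodes[[b]] <- ln
    }
    total <- adMeanOf(lossNodes)
    lv <- adVal(total)
    if (!is.finite(lv)) {
      warning(sprintf("non-finite loss at step %d; aborting with last good parameters", step))
      return(list(model = new("EpiModel", config = cfg, params = lastGood),
                  history = hist))
    }
    adBackward(total)
    grads <- lapply(pn, function(n) n$grad)
    upd <- adamStep(params, grads, opt, config@learningRate)
    params <- upd$params
    opt <- upd$state
    lastGood <- params
    hist <- rbind(hist, data.frame(step = step, loss = lv,
                                   mse = mseAcc / length(idx),
                                   csl = cslAcc / length(idx)))
    if (verbose && step %% 50 == 0)
      message(sprintf("step %d: loss %.5f (mse %.5f, csl %.5f)", step, lv,
                      mseAcc / length(idx), cslAcc / length(idx)))
  }
  list(model = new("EpiModel", config = cfg, params = params), history = hist)
}

## ---- frozen-backbone fine-tuning for pair classification ----

#' Anchor bins for pair fine-tuning
#'
#' All bins whose midpoint lies inside the anchor interval (0-based
#' half-open genomic coordinates), the rule behind the concatenated-feature
#' width.
#'
#' @param region the model window \code{BinnedRegion}.
#' @param anchorStart,anchorEnd anchor coordinates.
#' @export
anchorBins <- function(region, anchorStart, anchorEnd) {
  if (anchorStart < region@start || anchorEnd > region@end)
    stop("anchor outside the model window")
  mids <- region@start + (seq_len(region@nBins) - 0.5) * region@binSize
  which(mids >= anchorStart & mids < anchorEnd)
}

#' Pair features from frozen last-layer hidden states
#'
#' Concatenates the last-encoder-layer hidden vectors (width dModel) of all
#' bins selected for the two anchors; with a 5-kb anchor and the published
#' scale this is the high-dimensional fine-tuning feature.
#'
#' @param hidden tokens x dModel matrix from \code{\link{predictSignals}}.
#' @param binsA,binsB 1-based bin indices of the two anchors.
#' @export
pairFeatures <- function(hidden, binsA, binsB) {
  as.numeric(t(hidden[c(binsA, binsB), , drop = FALSE]))
}

#' Fine-tune a pair-classification head on a frozen backbone
#'
#' The backbone is never updated: features are last-layer hidden states of
#' anchor bins (\code{\link{pairFeatures}}); the head is a two-layer MLP
#' (default 256 hidden units per layer, ReLU) with a sigmoid output,
#' trained with Adam on binary cross-entropy.
#'
#' @param features n x F matrix of pair features.
#' @param labels 0/1 vector of length n.
#' @param hidden hidden units per MLP layer.
#' @param steps,learningRate,batchSize,seed optimization settings.
#' @return object of class \code{epHead}: \code{predict(head, features)}
#'   gives interaction probabilities.
#' @export
finetuneEP <- function(features, labels, hidden = 256L, steps = 300L,
                       learningRate = 1e-3, batchSize = 16L, seed = 1L) {
  features <- as.matrix(features)
  set.seed(seed)
  Fdim <- ncol(features)
  params <- list(W1 = rmat(Fdim, hidden), b1 = numeric(hidden),
                 W2 = rmat(hidden, hidden), b2 = numeric(hidden),
                 W3 = rmat(hidden, 1L), b3 = numeric(1L))
  opt <- adamInit(params)
  n <- nrow(features)
  for (step in seq_len(steps)) {
    idx <- sample.int(n, min(batchSize, n))
    tape <- adTape()
    pn <- paramLeaves(tape, params)
    x <- adLeaf(tape, features[idx, , drop = FALSE])
    z <- adReLU(adAdd(adMatmul(x, pn$W1), pn$b1))
    z <- adReLU(adAdd(adMatmul(z, pn$W2), pn$b2))
    z <- adAdd(adMatmul(z, pn$W3), pn$b3)
    loss <- adBCEWithLogits(z, matrix(labels[idx], ncol = 1))
    adBackward(loss)
    upd <- adamStep(params, lapply(pn, function(nn) nn$grad), opt, learningRate)
    params <- upd$params; opt <- upd$state
  }
  structure(list(params = params), class = "epHead")
}

#' @describeIn finetuneEP predict interaction probabilities.
#' @param object an \code{epHead}.
#' @param newdata n x F feature matrix.
#' @param ... unused.
#' @export
predict.epHead <- function(object, newdata, ...) {
  p <- object$params
  relu <- function(x) pmax(x, 0)
  z <- relu(sweep(as.matrix(newdata) %*% p$W1, 2, p$b1, `+`))
  z <- relu(sweep(z %*% p$W2, 2, p$b2, `+`))
  z <- sweep(z %*% p$W3, 2, p$b3, `+`)
  as.numeric(1 / (1 + exp(-z)))
}
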