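# Cell-type-wise metrics and experiment scaffolding: PCC/SCC/PSR per
# context, auROC/auPRC with macro averaging, distance stratification and
# distance-matched negative sampling.

#' Prediction squared error (an R-squared-type score)
#'
#' \eqn{1 - \sum_l (y_l - \hat y_l)^2 / \sum_l (y_l - \bar y)^2} about the
#' per-context mean: 1 for perfect prediction, 0 for predicting the mean,
#' negative when worse than the mean. Undefined (NA) for constant truth.
#'
#' @param y truth vector for one context.
#' @param yhat predictions.
#' @return scalar <= 1, or NA when y is constant.
#' @export
psr <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("at least two points required")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}

#' Cell-type-wise regression metrics
#'
#' PCC, SCC (average-tie Spearman) and PSR per context column, computed
#' over all loci of that context; masked-out cells are excluded. Columns
#' with fewer than two valid points get NA metrics.
#'
#' @param Y,Yhat loci x contexts truth and prediction matrices.
#' @param mask optional loci x contexts logical matrix (TRUE = valid); or a
#'   length-ncol logical vector marking whole contexts.
#' @return data.frame with columns context, pcc, scc, psr.
#' @export
celltypeMetrics <- function(Y, Yhat, mask = NULL) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("shape mismatch")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(Y), ncol(Y))
  if (is.vector(mask)) mask <- matrix(mask, nrow(Y), ncol(Y), byrow = TRUE)
  ctx <- colnames(Y)
  if (is.null(ctx)) ctx <- paste0("context", seq_len(ncol(Y)))
  out <- data.frame(context = ctx, pcc = NA_real_, scc = NA_real_,
                    psr = NA_real_)
  for (k in seq_len(ncol(Y))) {
    ok <- which(mask[, k])
    if (length(ok) < 2) next
    y <- Y[ok, k]; yh <- Yhat[ok, k]
    if (stats::sd(y) > 0 && stats::sd(yh) > 0) {
      out$pcc[k] <- stats::cor(y, yh)
      out$scc[k] <- stats::cor(y, yh, method = "spearman")
    }
    out$psr[k] <- psr(y, yh)
  }
  out
}

#' Binary classification metrics: auROC and auPRC
#'
#' Trapezoidal area under the ROC curve and step-wise (rectangular) area
#' under the precision-recall curve. With a matrix of labels/scores, one
#' metric per column plus unweighted macro averages. Columns with a single
#' class get NA and a flag.
#'
#' @param labels 0/1 vector, or loci x classes matrix.
#' @param scores numeric vector or matrix matching \code{labels}.
#' @return for vectors: list(auroc, auprc); for matrices: list(perClass
#'   data.frame, macro list, singleClass logical flags).
#' @export
binaryMetrics <- function(labels, scores) {
  if (is.matrix(labels) || is.data.frame(labels)) {
    labels <- as.matrix(labels); scores <- as.matrix(scores)
    per <- data.frame(class = colnames(labels) %||% paste0("class", seq_len(ncol(labels))),
                      auroc = NA_real_, auprc = NA_real_)
    for (k in seq_len(ncol(labels))) {
      m <- binaryMetricsVector(labels[, k], scores[, k])
      per$auroc[k] <- m$auroc; per$auprc[k] <- m$auprc
    }
    single <- is.na(per$auroc)
    return(list(perClass = per,
                macro = list(auroc = mean(per$auroc, na.rm = TRUE),
                             auprc = mean(per$auprc, na.rm = TRUE)),
                singleClass = single))
  }
  binaryMetricsVector(labels, scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

binaryMetricsVector <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    return(list(auroc = NA_real_, auprc = NA_real_))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  P <- sum(lab == 1); N <- sum(lab == 0)
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  # evaluate at distinct-threshold boundaries
  keep <- c(diff(sc) != 0, TRUE)
  tp <- c(0, tp[keep]); fp <- c(0, fp[keep])
  tpr <- tp / P; fpr <- fp / N
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  rec <- tpr
  auprc <- sum(diff(rec) * utils::tail(prec, -1))   # step-wise
  list(auroc = auroc, auprc = auprc)
}

#' Distance band of an element-gene pair
#'
#' Half-open bands \code{[lo, hi)}; the published stratification is
#' 0-20 kb, 20-40 kb and 40-64 kb, with pairs beyond the last edge
#' excluded as \code{"out_of_range"}.
#'
#' @param distance non-negative distance(s) in bp.
#' @param bands vector of band edges (default \code{c(0, 20000, 40000, 64000)}).
#' @return character vector of band labels.
#' @export
distanceBand <- function(distance, bands = c(0, 20000, 40000, 64000)) {
  if (any(distance < 0)) stop("distance must be non-negative")
  labs <- paste0(utils::head(bands, -1) / 1000, "-",
                 utils::tail(bands, -1) / 1000, "kbp")
  idx <- findInterval(distance, bands, rightmost.closed = FALSE)
  out <- ifelse(idx >= 1 & idx < length(bands), labs[pmax(idx, 1)],
                "out_of_range")
  out
}

#' Mirror a positive anchor to a distance-matched negative
#'
#' The negative anchor sits at the same distance from the TSS but in the
#' opposite direction, so positives and negatives have identical distance
#' distributions by construction. Mirrors falling outside
#' \code{[windowStart, windowEnd)} (or landing on the TSS itself) are
#' rejected with NA.
#'
#' @param tss TSS coordinate.
#' @param anchor positive anchor coordinate.
#' @param windowStart,windowEnd admissible range for the mirrored anchor.
#' @return mirrored coordinate, or NA when invalid.
#' @export
matchedNegative <- function(tss, anchor, windowStart = -Inf, windowEnd = Inf) {
  neg <- tss - (anchor - tss)
  invalid <- anchor == tss | neg < windowStart | neg >= windowEnd
  ifelse(invalid, NA_real_, neg)
}

#' Distance-matched negative sampling from a candidate pool
#'
#' Samples as many negatives as there are positives, stratified so the
#' negative distance histogram (over the given bands) matches the positive
#' one. Errors if a needed band has too few pool candidates.
#'
#' @param positiveDistances distances of positive pairs.
#' @param poolDistances distances of candidate negative pairs.
#' @param bands distance-band edges (see \code{\link{distanceBand}}).
#' @param seed RNG seed.
#' @return indices into the pool, of length \code{length(positiveDistances)}.
#' @export
matchedNegativeDistribution <- function(positiveDistances, poolDistances,
                                        bands = c(0, 20000, 40000, 64000),
                                        seed = 1L) {
  set.seed(seed)
  pb <- distanceBand(positiveDistances, bands)
  qb <- distanceBand(poolDistances, bands)
  out <- integer(0)
  for (b in unique(pb)) {
    need <- sum(pb == b)
    cand <- which(qb == b)
    if (length(cand) < need)
      stop(sprintf("band %s: %d candidates for %d positives", b,
                   length(cand), need))
    out <- c(out, sample(cand, need))
  }
  out
}

#' Context-level k-fold splitter
#'
#' Partitions contexts (not loci) into k folds for cross-context
#' validation; every context appears in exactly one fold, reproducibly for
#' a given seed.
#'
#' @param contexts character vector of context names.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of k character vectors.
#' @export
contextFolds <- function(contexts, k = 5L, seed = 1L) {
  set.seed(seed)
  perm <- sample(contexts)
  split(perm, rep_len(seq_len(k), length(perm)))
}
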