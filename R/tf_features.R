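# The context token: per-bin motif max-scores x per-context expression.

#' Construct a PWMSet
#'
#' @param pwms named list of width x 4 log-odds matrices (columns A,C,G,T).
#' @return A \code{\linkS4class{PWMSet}}.
#' @export
PWMSet <- function(pwms) {
  pwms <- lapply(pwms, function(m) {
    m <- as.matrix(m); colnames(m) <- c("A", "C", "G", "T"); m
  })
  new("PWMSet", pwms = pwms)
}

#' @describeIn PWMSet number of motifs.
#' @param x a \code{PWMSet}.
#' @export
setMethod("length", "PWMSet", function(x) length(x@pwms))

#' @describeIn PWMSet motif (TF) names.
#' @export
setMethod("names", "PWMSet", function(x) names(x@pwms))

#' @describeIn PWMSet extract one PWM by name or index.
#' @param i index or name.
#' @export
setMethod("[[", "PWMSet", function(x, i) x@pwms[[i]])

setMethod("show", "PWMSet", function(object) {
  w <- vapply(object@pwms, nrow, 1L)
  cat(sprintf("PWMSet of %d motifs (widths %d-%d)\n",
              length(object@pwms), min(w), max(w)))
})

#' Log-odds PWM from base counts
#'
#' \code{log2((counts + pseudocount) / colsum / background)} per position,
#' uniform background 0.25 by default.
#'
#' @param counts width x 4 count matrix (columns A,C,G,T).
#' @param pseudocount added to every cell before normalization.
#' @param background length-4 background probabilities.
#' @export
pwmFromCounts <- function(counts, pseudocount = 0.25,
                          background = rep(0.25, 4)) {
  counts <- as.matrix(counts) + pseudocount
  p <- counts / rowSums(counts)
  lo <- log2(sweep(p, 2, background, `/`))
  colnames(lo) <- c("A", "C", "G", "T")
  lo
}

#' Read PWMs from a JASPAR-style or 4-row matrix text file
#'
#' Accepts blocks introduced by \code{>name}, each followed by four rows in
#' A,C,G,T order; rows may be bare numbers or JASPAR's
#' \code{A [ 1 2 3 ]} style. Count matrices (all entries >= 0 and integer-ish
#' with column sums > 1) are converted to log-odds via
#' \code{\link{pwmFromCounts}}; matrices containing negatives are taken as
#' log-odds already.
#'
#' @param path motif file path.
#' @return A \code{\linkS4class{PWMSet}}.
#' @export
readPWMs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) stop("no '>' motif headers found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- list()
  for (b in seq_along(starts)) {
    nm <- strsplit(sub("^>\\s*", "", lines[starts[b]]), "\\s+")[[1]][1]
    body <- lines[(starts[b] + 1L):ends[b]]
    if (length(body) != 4)
      stop(sprintf("motif '%s': expected 4 base rows, got %d", nm, length(body)))
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop(sprintf("motif '%s': ragged rows", nm))
    m <- t(do.call(rbind, rows))        # width x 4, base rows were A,C,G,T
    colnames(m) <- c("A", "C", "G", "T")
    if (all(m >= 0) && all(abs(m - round(m)) < 1e-8) && all(rowSums(m) > 1))
      m <- pwmFromCounts(m)
    pwms[[nm]] <- m
  }
  PWMSet(pwms)
}

#' Write a PWMSet in the JASPAR-like format readPWMs accepts
#'
#' @param pwmSet a \code{PWMSet}.
#' @param path output path.
#' @export
writePWMs <- function(pwmSet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pwmSet)) {
    m <- pwmSet[[nm]]
    writeLines(paste0(">", nm), con)
    for (j in 1:4)
      writeLines(paste(c("A", "C", "G", "T")[j], "[",
                       paste(sprintf("%.17g", m[, j]), collapse = " "), "]"), con)
  }
  invisible(path)
}

# Per-base log-odds rows for a sequence: L x width matrix whose [i, t] entry
# is pwm[t, base_i]; ambiguous bases contribute 0.
pwmBaseScores <- function(pwm, onehot) onehot %*% t(pwm)

#' Maximal PWM match score within a bin
#'
#' Scans every offset at which the motif fits inside the bin, sums the
#' log-odds at that offset, takes the maximum, and floors at 0 (no reported
#' binding scores 0). Forward strand by default.
#'
#' @param pwm width x 4 log-odds matrix.
#' @param binSeq bin sequence (character) or a one-hot matrix.
#' @param bothStrands also scan the reverse complement.
#' @return a single non-negative score.
#' @export
scanMaxScore <- function(pwm, binSeq, bothStrands = FALSE) {
  oh <- if (is.matrix(binSeq)) binSeq else oneHotSequence(binSeq)
  w <- nrow(pwm)
  if (nrow(oh) < w) {
    warning("bin shorter than motif width; scoring 0")
    return(0)
  }
  sc <- slidingPwmScores(pwm, oh)
  if (bothStrands)
    sc <- pmax(sc, slidingPwmScores(reverseComplementPwm(pwm), oh))
  max(0, max(sc))
}

slidingPwmScores <- function(pwm, onehot) {
  w <- nrow(pwm)
  L <- nrow(onehot)
  M <- pwmBaseScores(pwm, onehot)
  sc <- numeric(L - w + 1L)
  for (t in seq_len(w)) sc <- sc + M[t:(t + L - w), t]
  sc
}

reverseComplementPwm <- function(pwm) {
  m <- pwm[rev(seq_len(nrow(pwm))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  m
}

#' Per-bin motif max-score matrix for a window
#'
#' Scores every bin of \code{region} against every motif
#' (\code{\link{scanMaxScore}} per bin; motif occurrences must fit inside a
#' bin). Returns a bins x nTF non-negative matrix.
#'
#' @param pwmSet a \code{PWMSet}.
#' @param windowSeq sequence of the whole window (character or
#'   \code{DNAString}), length \code{nBins * binSize}.
#' @param region the \code{BinnedRegion} (or just the bin size).
#' @param bothStrands also scan reverse complements.
#' @export
motifScoreMatrix <- function(pwmSet, windowSeq, region, bothStrands = FALSE) {
  oh <- if (is.matrix(windowSeq)) windowSeq else oneHotSequence(windowSeq)
  bs <- if (is(region, "BinnedRegion")) region@binSize else region
  L <- nrow(oh)
  if (L %% bs != 0) stop("window length must be a multiple of the bin size")
  nb <- L %/% bs
  out <- matrix(0, nb, length(pwmSet), dimnames = list(NULL, names(pwmSet)))
  for (ti in seq_along(pwmSet@pwms)) {
    pwm <- pwmSet@pwms[[ti]]
    w <- nrow(pwm)
    if (w > bs) { warning("motif wider than bin; scoring 0"); next }
    sc <- slidingPwmScores(pwm, oh)
    if (bothStrands)
      sc <- pmax(sc, slidingPwmScores(reverseComplementPwm(pwm), oh))
    for (j in seq_len(nb)) {
      o1 <- (j - 1L) * bs + 1L
      out[j, ti] <- max(0, max(sc[o1:(o1 + bs - w)]))
    }
  }
  out
}

#' Quantile-normalize a TPM table after log1p
#'
#' Applies \code{log1p} then classical quantile normalization: each column
#' is mapped onto the mean of the sorted columns, ties receiving the mean of
#' the reference values they span (limma's average-ties policy).
#'
#' @param tpm genes x contexts non-negative matrix.
#' @return matrix of the same shape.
#' @export
quantileNormalizeTPM <- function(tpm) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  x <- log1p(as.matrix(tpm))
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(tpm)
  out
}

# Next even integer >= n: the published profile pads 711 TFs to width 712.
padTFWidth <- function(nTF) as.integer(nTF + nTF %% 2)

#' Build a TFFeatureBlock
#'
#' @param motifScores bins x nTF non-negative max-score matrix.
#' @param expression contexts x nTF expression matrix (rows are contexts),
#'   conventionally quantile-normalized log1p TPM.
#' @param nTFPadded model TF width; default pads to the next even value.
#' @return A \code{\linkS4class{TFFeatureBlock}}.
#' @export
TFFeatureBlock <- function(motifScores, expression,
                           nTFPadded = padTFWidth(ncol(motifScores))) {
  new("TFFeatureBlock", motifScores = as.matrix(motifScores),
      expression = as.matrix(expression), nTFPadded = as.integer(nTFPadded))
}

#' @describeIn TFFeatureBlock bins x nTF motif max-score matrix.
#' @param x a \code{TFFeatureBlock}.
#' @export
setMethod("motifScores", "TFFeatureBlock", function(x) x@motifScores)

#' @describeIn TFFeatureBlock contexts x nTF expression matrix.
#' @export
setMethod("tfExpression", "TFFeatureBlock", function(x) x@expression)

setMethod("show", "TFFeatureBlock", function(object) {
  cat(sprintf("TFFeatureBlock: %d bins x %d TFs (padded to %d), %d contexts\n",
              nrow(object@motifScores), ncol(object@motifScores),
              object@nTFPadded, nrow(object@expression)))
})

#' Combine motif scores with one context's expression
#'
#' The model's TF input: element-wise product
#' \code{out[j, t] = motif[j, t] * expr[t]} broadcast over bins, then
#' zero-padded to \code{nTFPadded} columns (so 711 TFs become width 712 at
#' the published scale).
#'
#' @param motifScores bins x nTF matrix.
#' @param expressionRow length-nTF expression vector for one context.
#' @param nTFPadded output width (>= nTF).
#' @return bins x nTFPadded matrix; padded columns are exactly zero.
#' @export
combineTF <- function(motifScores, expressionRow,
                      nTFPadded = padTFWidth(ncol(motifScores))) {
  nTF <- ncol(motifScores)
  if (length(expressionRow) != nTF)
    stop(sprintf("expression length %d does not match nTF %d",
                 length(expressionRow), nTF))
  if (nTFPadded < nTF) stop("nTFPadded must be >= nTF")
  out <- matrix(0, nrow(motifScores), nTFPadded)
  out[, seq_len(nTF)] <- motifScores *
    matrix(expressionRow, nrow(motifScores), nTF, byrow = TRUE)
  out
}

#' @describeIn combineTF combined input for one context of a
#'   \code{TFFeatureBlock}.
#' @param block a \code{TFFeatureBlock}.
#' @param context context row name or index.
#' @export
combinedFeatures <- function(block, context) {
  ci <- if (is.character(context)) match(context, rownames(block@expression)) else context
  if (is.na(ci)) stop("unknown context")
  combineTF(block@motifScores, block@expression[ci, ], block@nTFPadded)
}
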