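#' Partition a genomic window into fixed-width bins
#'
#' Builds the coordinate frame used everywhere downstream. Coordinates are
#' 0-based half-open (BED convention); bin \code{j} (1-based) covers
#' \code{[start + (j-1)*binSize, start + j*binSize)}. At the published scale
#' a 128,000-bp window with 128-bp bins yields 1000 bins.
#'
#' @param chrom chromosome name.
#' @param start,end window coordinates, 0-based half-open; \code{end - start}
#'   must be an exact multiple of \code{binSize}.
#' @param binSize bin width in bp.
#' @return A \code{\linkS4class{BinnedRegion}}.
#' @examples
#' makeBins("chr1", 0, 128000, 128)   # 1000 bins
#' @export
makeBins <- function(chrom, start, end, binSize) {
  if (length(binSize) != 1 || binSize <= 0)
    stop("binSize must be a single positive number")
  if (end <= start)
    stop("end must exceed start")
  span <- end - start
  if (span %% binSize != 0)
    stop(sprintf("window span %d is not divisible by binSize %d (remainder %d)",
                 span, binSize, span %% binSize))
  new("BinnedRegion", chrom = as.character(chrom), start = start, end = end,
      binSize = binSize, nBins = as.integer(span %/% binSize))
}

#' @describeIn makeBins number of bins.
#' @param x a \code{BinnedRegion}.
#' @export
setMethod("nBins", "BinnedRegion", function(x) x@nBins)

#' @describeIn makeBins bin width in bp.
#' @export
setMethod("binSize", "BinnedRegion", function(x) x@binSize)

#' @describeIn makeBins bins as a \code{GRanges} (1-based closed, as usual
#'   for Bioconductor ranges).
#' @export
setMethod("binRanges", "BinnedRegion", function(x) {
  starts0 <- x@start + (seq_len(x@nBins) - 1) * x@binSize
  GenomicRanges::GRanges(x@chrom,
    IRanges::IRanges(start = starts0 + 1, width = x@binSize))
})

setMethod("show", "BinnedRegion", function(object) {
  cat(sprintf("BinnedRegion %s:%d-%d | %d bins of %d bp\n",
              object@chrom, object@start, object@end,
              object@nBins, object@binSize))
})

#' 1-based bin index of a 0-based genomic position
#'
#' @param region a \code{BinnedRegion}.
#' @param pos 0-based position(s); must lie inside the region.
#' @export
binIndexOf <- function(region, pos) {
  if (any(pos < region@start | pos >= region@end))
    stop("position outside the binned region")
  as.integer((pos - region@start) %/% region@binSize) + 1L
}

#' Construct a CountMatrix
#'
#' @param counts loci x contexts matrix of raw read counts.
#' @param depths per-context total pooled read counts (library sizes).
#' @return A \code{\linkS4class{CountMatrix}}.
#' @export
CountMatrix <- function(counts, depths) {
  new("CountMatrix", counts = as.matrix(counts), depths = as.numeric(depths))
}

#' Sequencing-depth normalization of raw counts
#'
#' Rescales raw counts so contexts are comparable across library sizes:
#' \eqn{\tilde n_{lk} = N \, n_{lk} / N_k} with \eqn{N = \min_k N_k}, i.e.
#' every context is brought down to the shallowest library. The
#' minimum-depth context is returned unchanged; with a single context the
#' output equals the input.
#'
#' @param cm a \code{\linkS4class{CountMatrix}}.
#' @return loci x contexts numeric matrix of normalized counts.
#' @export
normalizeCounts <- function(cm) {
  stopifnot(is(cm, "CountMatrix"))
  if (any(cm@depths <= 0)) stop("all depths must be positive")
  N <- min(cm@depths)
  sweep(cm@counts, 2, N / cm@depths, `*`)
}

#' log1p transform of non-negative signal
#'
#' \code{log(x + 1)} elementwise ("log transformed with pseudo count 1").
#'
#' @param x non-negative numeric array.
#' @export
log1pSignal <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("log1pSignal requires non-negative input")
  log1p(x)
}

#' Binarize raw counts at a strict threshold
#'
#' Label 1 iff the raw read count is strictly greater than \code{threshold}
#' (default 30), marking a bin as an accessible/active region.
#'
#' @param raw non-negative integer array of raw counts.
#' @param threshold strict cutoff; \code{raw > threshold} maps to 1.
#' @return integer array of 0/1 labels, same shape as \code{raw}.
#' @export
binarizeCounts <- function(raw, threshold = 30) {
  if (any(raw < 0, na.rm = TRUE)) stop("raw counts must be non-negative")
  out <- ifelse(raw > threshold, 1L, 0L)
  attributes(out) <- attributes(raw)
  out
}

#' One-hot encode a DNA sequence
#'
#' Columns in fixed A,C,G,T order; canonical bases map to unit rows
#' (A=[1,0,0,0], C=[0,1,0,0], G=[0,0,1,0], T=[0,0,0,1]), \code{N} maps to an
#' all-zero row, lowercase is accepted. Any other character is rejected with
#' its position.
#'
#' @param seq a single DNA string (character or \code{DNAString}).
#' @return length x 4 integer matrix with colnames A,C,G,T.
#' @export
oneHotSequence <- function(seq) {
  s <- toupper(as.character(seq))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("non-IUPAC character '%s' at position %d", ch[bad], bad))
  }
  m <- matrix(0L, length(ch), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  known <- idx <= 4L
  m[cbind(which(known), idx[known])] <- 1L
  m
}

#' Assemble a SignalTensor from BED loci and per-track count tables
#'
#' Loci (one per bin of \code{region}) come from a BED file; each measured
#' (context, signal) track contributes raw counts and a library depth.
#' Counts are depth-normalized across the contexts in which the signal was
#' measured (\code{\link{normalizeCounts}}) and log1p-transformed. Tracks
#' absent from \code{countTable} get \code{mask = FALSE} and zero values.
#'
#' @param bedPath BED file of loci; each interval must coincide with a bin
#'   of \code{region}.
#' @param countTable data frame (or TSV path) with columns
#'   \code{locus_id, context, signal, count, depth}; \code{locus_id} refers
#'   to the BED name column (or line number when names are absent).
#' @param region a \code{BinnedRegion}.
#' @param signals ordered signal panel (default \code{DEFAULT_SIGNALS}).
#' @param contexts ordered contexts; default: those present in the table.
#' @return A \code{\linkS4class{SignalTensor}}.
#' @export
loadSignals <- function(bedPath, countTable, region,
                        signals = DEFAULT_SIGNALS, contexts = NULL) {
  loci <- readBedRegions(bedPath)
  st0 <- GenomicRanges::start(loci) - 1L
  en0 <- GenomicRanges::end(loci)
  if (any(st0 < region@start | en0 > region@end))
    stop("BED locus coordinates fall outside the binned region")
  if (any((st0 - region@start) %% region@binSize != 0 |
          (en0 - st0) != region@binSize))
    stop("each BED locus must coincide with one bin of the region")
  ids <- names(loci)
  if (is.null(ids) || any(ids == "" | is.na(ids))) ids <- as.character(seq_along(loci))
  binOf <- stats::setNames(binIndexOf(region, st0), ids)

  if (is.character(countTable))
    countTable <- utils::read.delim(countTable, stringsAsFactors = FALSE)
  need <- c("locus_id", "context", "signal", "count", "depth")
  if (!all(need %in% names(countTable)))
    stop("countTable must have columns ", paste(need, collapse = ", "))
  if (is.null(contexts)) contexts <- sort(unique(countTable$context))
  unknown <- setdiff(unique(countTable$locus_id), ids)
  if (length(unknown))
    stop("count table references unknown loci: ", paste(unknown, collapse = ", "))

  nb <- region@nBins
  vals <- array(0, c(length(contexts), nb, length(signals)))
  mask <- matrix(FALSE, length(contexts), length(signals),
                 dimnames = list(contexts, signals))
  for (k in seq_along(signals)) {
    sub <- countTable[countTable$signal == signals[k], , drop = FALSE]
    if (!nrow(sub)) next
    have <- intersect(contexts, unique(sub$context))
    if (!length(have)) next
    cnt <- matrix(0, nb, length(have), dimnames = list(NULL, have))
    dep <- numeric(length(have)); names(dep) <- have
    for (cc in have) {
      rows <- sub[sub$context == cc, , drop = FALSE]
      cnt[binOf[as.character(rows$locus_id)], cc] <- rows$count
      dep[cc] <- rows$depth[1]
    }
    proc <- log1pSignal(normalizeCounts(CountMatrix(cnt, dep)))
    for (cc in have) {
      ci <- match(cc, contexts)
      vals[ci, , k] <- proc[, cc]
      mask[ci, k] <- TRUE
    }
  }
  new("SignalTensor", values = vals, mask = mask, signalNames = signals,
      contexts = as.character(contexts), region = region)
}

#' Construct a SignalTensor directly from arrays
#'
#' @param values contexts x bins x signals array.
#' @param mask contexts x signals logical matrix.
#' @param signals,contexts dimension names.
#' @param region the \code{BinnedRegion}.
#' @export
SignalTensor <- function(values, mask, signals, contexts, region) {
  new("SignalTensor", values = values, mask = mask,
      signalNames = signals, contexts = contexts, region = region)
}

#' @describeIn SignalTensor signal panel names.
#' @param x a \code{SignalTensor}.
#' @export
setMethod("signalNames", "SignalTensor", function(x) x@signalNames)

#' @describeIn SignalTensor context identifiers.
#' @export
setMethod("contextNames", "SignalTensor", function(x) x@contexts)

#' @describeIn SignalTensor contexts x signals logical availability matrix.
#' @export
setMethod("availabilityMask", "SignalTensor", function(x) x@mask)

#' @describeIn SignalTensor bins x signals value matrix for one context (or
#'   one context/signal vector when \code{signal} is given).
#' @param context context name or index.
#' @param signal optional signal name or index.
#' @export
setMethod("signalValues", "SignalTensor", function(x, context, signal) {
  ci <- if (is.character(context)) match(context, x@contexts) else context
  if (is.na(ci)) stop("unknown context")
  m <- x@values[ci, , , drop = TRUE]
  m <- matrix(m, nBins(x@region), length(x@signalNames),
              dimnames = list(NULL, x@signalNames))
  if (missing(signal)) return(m)
  m[, signal]
})

setMethod("show", "SignalTensor", function(object) {
  cat(sprintf("SignalTensor: %d contexts x %d bins x %d signals (%.0f%% tracks available)\n",
              length(object@contexts), nBins(object@region),
              length(object@signalNames), 100 * mean(object@mask)))
})

#' Read regions from a BED file
#'
#' Thin wrapper over \code{rtracklayer} BED import returning a
#' \code{GRanges}; interval names come from the BED name column.
#'
#' @param path BED file path.
#' @export
readBedRegions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Write regions to a BED file
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @export
writeBedRegions <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

## ---- plain-text signal container ----
# One self-describing text file: a JSON header line (region, bin size,
# contexts, signals), the mask block, then one full-precision (%.17g) value
# line per (context, signal). Round-trips bit-exactly.

#' Write a SignalTensor to its text container
#'
#' @param st a \code{SignalTensor}.
#' @param path output path (conventionally \code{.signals.tsv}).
#' @export
writeSignalTensor <- function(st, path) {
  hdr <- jsonlite::toJSON(list(
    format = "epicontext-signals", version = 1L,
    chrom = st@region@chrom, start = st@region@start, end = st@region@end,
    binSize = st@region@binSize, contexts = st@contexts,
    signals = st@signalNames), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#HEADER\t", hdr), con)
  for (ci in seq_along(st@contexts))
    writeLines(paste0("#MASK\t", st@contexts[ci], "\t",
                      paste(as.integer(st@mask[ci, ]), collapse = "\t")), con)
  for (ci in seq_along(st@contexts))
    for (k in seq_along(st@signalNames))
      writeLines(paste(st@contexts[ci], st@signalNames[k],
                       paste(sprintf("%.17g", st@values[ci, , k]), collapse = "\t"),
                       sep = "\t"), con)
  invisible(path)
}

#' Read a SignalTensor from its text container
#'
#' @param path file written by \code{\link{writeSignalTensor}}.
#' @export
readSignalTensor <- function(path) {
  lines <- readLines(path)
  hline <- sub("^#HEADER\t", "", lines[startsWith(lines, "#HEADER")])
  if (!length(hline)) stop("missing #HEADER line: not a signal container")
  hdr <- jsonlite::fromJSON(hline)
  region <- makeBins(hdr$chrom, hdr$start, hdr$end, hdr$binSize)
  contexts <- hdr$contexts; signals <- hdr$signals
  mask <- matrix(FALSE, length(contexts), length(signals),
                 dimnames = list(contexts, signals))
  for (ln in lines[startsWith(lines, "#MASK")]) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    mask[p[2], ] <- as.integer(p[-(1:2)]) == 1L
  }
  vals <- array(0, c(length(contexts), region@nBins, length(signals)))
  for (ln in lines[!startsWith(lines, "#")]) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    ci <- match(p[1], contexts); k <- match(p[2], signals)
    if (is.na(ci) || is.na(k)) stop("value line references unknown context/signal")
    vals[ci, , k] <- as.numeric(p[-(1:2)])
  }
  SignalTensor(vals, mask, signals, contexts, region)
}
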