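# Fixture generator: random genomes with planted motif sites, contexts
# whose TF expression determines which sites are active, signals generated
# as a known softplus function of (motif score x expression), planted
# contacts from element bins to a designated TSS bin, and motif-destroying
# vs neutral variants. Everything is emitted in the formats the pipeline
# ingests, plus a truth list for recovery tests.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Simulation configuration
#'
#' The default world is the desk-scale fixture: a 512-kb genome in 128-bp
#' bins split into 4096-bp model windows, 8 TFs of which 2 are planted
#' regulators (each window is driven by exactly one of them), 6 cellular
#' contexts alternating which regulator is active, and the default 8-signal
#' panel. Signals are
#' \code{softplus(sum_t W[t,k] motif[j,t] expr[c,t])}, smoothed over
#' \code{smoothWidth} flanking bins, plus Gaussian noise clamped at 0.
#'
#' @param seed RNG seed; runs are bit-reproducible given it.
#' @param genomeLength,binSize,windowSize genome geometry in bp.
#' @param nTFs,nPlantedRegulators TF panel size and planted drivers.
#' @param nContexts cellular contexts (active regulator alternates).
#' @param signals signal names (length K).
#' @param motifWidth planted consensus width.
#' @param sitesPerWindow planted motif sites per window.
#' @param signalWeight W entry for planted regulators.
#' @param smoothWidth half-width s of the +-s bin moving average.
#' @param noiseSd Gaussian noise sd on the signal scale.
#' @param maskRate fraction of (context, signal) tracks masked missing.
#' @param nEffectVariants,nNeutralVariants SNV counts of each kind.
#' @return a \code{simConfig} list.
#' @export
simConfig <- function(seed = 1L, genomeLength = 512000, binSize = 128,
                      windowSize = 4096, nTFs = 8L, nPlantedRegulators = 2L,
                      nContexts = 6L, signals = DEFAULT_SIGNALS,
                      motifWidth = 8L, sitesPerWindow = 2L,
                      signalWeight = 0.15, smoothWidth = 1L, noiseSd = 0.05,
                      maskRate = 0.25, nEffectVariants = 12L,
                      nNeutralVariants = 12L) {
  stopifnot(genomeLength %% windowSize == 0, windowSize %% binSize == 0,
            nPlantedRegulators >= 1, nPlantedRegulators <= nTFs,
            noiseSd >= 0, maskRate >= 0, maskRate < 1)
  structure(as.list(environment()), class = "simConfig")
}

# Sharp PWM whose consensus is a fixed base string: 85% consensus base.
consensusPwm <- function(consensus) {
  w <- nchar(consensus)
  counts <- matrix(5, w, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  counts[cbind(seq_len(w), idx)] <- 85
  pwmFromCounts(counts)
}

#' Simulate a regulome with planted, recoverable structure
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir optional directory; when given, all pipeline input files are
#'   written there (FASTA, BED, expression TSV, signal container, BEDPE
#'   loops, VCF, truth JSON) via \code{\link{writeSim}}.
#' @return a \code{regulomeSim} list: genome (character), \code{pwms}
#'   (\code{PWMSet}), \code{expression} (contexts x nTFs), \code{signals}
#'   (\code{SignalTensor} over the whole genome), \code{noiseFree} (same
#'   array without noise/masking), \code{motif} (bins x nTFs scores),
#'   \code{loops} (BEDPE-style data.frame), \code{variants} (data.frame),
#'   \code{truth} (list), \code{config}.
#' @export
simulateRegulome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  L <- config$genomeLength
  bs <- config$binSize
  nb <- L %/% bs
  nWin <- L %/% config$windowSize
  binsPerWin <- config$windowSize %/% bs
  if (config$sitesPerWindow > binsPerWin - 1L)
    stop(sprintf("cannot plant %d sites in %d available bins per window",
                 config$sitesPerWindow, binsPerWin - 1L))
  if (config$motifWidth > bs)
    stop("motif width exceeds the bin size")
  genome <- sample(bases, L, replace = TRUE)

  # motifs: planted regulators first, then bystander TFs
  tfNames <- sprintf("TF%02d", seq_len(config$nTFs))
  consensi <- vapply(seq_len(config$nTFs), function(i)
    paste(sample(bases, config$motifWidth, replace = TRUE), collapse = ""),
    "")
  pwms <- PWMSet(stats::setNames(lapply(consensi, consensusPwm), tfNames))

  # plant sites: window w is driven by regulator (w-1) %% nPlanted + 1
  regOfWindow <- (seq_len(nWin) - 1L) %% config$nPlantedRegulators + 1L
  elementBins <- vector("list", nWin)
  siteStarts <- vector("list", nWin)   # 0-based genomic starts of sites
  tssBin <- integer(nWin)
  for (w in seq_len(nWin)) {
    w0 <- (w - 1L) * config$windowSize
    localBins <- sample(setdiff(seq_len(binsPerWin), binsPerWin %/% 2L + 1L),
                        config$sitesPerWindow)
    tssBin[w] <- (w - 1L) * binsPerWin + binsPerWin %/% 2L + 1L
    cons <- strsplit(consensi[regOfWindow[w]], "")[[1]]
    starts <- integer(config$sitesPerWindow)
    for (si in seq_along(localBins)) {
      off <- sample.int(bs - config$motifWidth, 1L) - 1L
      s0 <- w0 + (localBins[si] - 1L) * bs + off
      genome[s0 + seq_len(config$motifWidth)] <- cons
      starts[si] <- s0
    }
    elementBins[[w]] <- (w - 1L) * binsPerWin + localBins
    siteStarts[[w]] <- starts
  }
  genomeStr <- paste(genome, collapse = "")

  # expression: planted regulator active in alternating contexts
  expr <- matrix(stats::runif(config$nContexts * config$nTFs, 0.5, 1.5),
                 config$nContexts, config$nTFs,
                 dimnames = list(sprintf("ctx%d", seq_len(config$nContexts)),
                                 tfNames))
  classOfContext <- (seq_len(config$nContexts) - 1L) %%
    config$nPlantedRegulators + 1L
  for (r in seq_len(config$nPlantedRegulators)) {
    on <- classOfContext == r
    expr[on, r] <- stats::runif(sum(on), 1.5, 2.5)
    expr[!on, r] <- stats::runif(sum(!on), 0, 0.1)
  }

  # signals: softplus link on motif x expression, planted regulators only
  region <- makeBins("chrSim", 0, L, bs)
  motif <- motifScoreMatrix(pwms, genomeStr, region)
  K <- length(config$signals)
  W <- matrix(0, config$nTFs, K, dimnames = list(tfNames, config$signals))
  W[seq_len(config$nPlantedRegulators), ] <- config$signalWeight
  noiseFree <- array(0, c(config$nContexts, nb, K))
  for (ci in seq_len(config$nContexts)) {
    act <- motif %*% (W * expr[ci, ])       # bins x K
    sp <- softplus(act)
    if (config$smoothWidth > 0) {
      kwin <- 2L * config$smoothWidth + 1L
      sp <- apply(sp, 2, function(v)
        stats::filter(v, rep(1 / kwin, kwin), sides = 2) |>
          (\(x) { x[is.na(x)] <- v[is.na(x)]; x })())
    }
    noiseFree[ci, , ] <- sp
  }
  values <- noiseFree
  if (config$noiseSd > 0)
    values <- pmax(values + stats::rnorm(length(values), sd = config$noiseSd), 0)

  mask <- matrix(stats::runif(config$nContexts * K) >= config$maskRate,
                 config$nContexts, K,
                 dimnames = list(rownames(expr), config$signals))
  for (ci in which(rowSums(mask) == 0)) mask[ci, sample.int(K, 1L)] <- TRUE
  st <- SignalTensor(values, mask, config$signals, rownames(expr), region)

  # planted loops: element bins <-> TSS bin, plus sub-threshold decoys
  loops <- list()
  for (w in seq_len(nWin)) {
    for (b in elementBins[[w]]) {
      loops[[length(loops) + 1L]] <- data.frame(
        chrom1 = "chrSim", start1 = (b - 1L) * bs, end1 = b * bs,
        chrom2 = "chrSim", start2 = (tssBin[w] - 1L) * bs,
        end2 = tssBin[w] * bs,
        score = stats::runif(1, 2, 5), qvalue = 1e-4)
    }
    decoy <- sample(setdiff(seq_len(binsPerWin), 1L), 1L) +
      (w - 1L) * binsPerWin
    loops[[length(loops) + 1L]] <- data.frame(
      chrom1 = "chrSim", start1 = (decoy - 1L) * bs, end1 = decoy * bs,
      chrom2 = "chrSim", start2 = (tssBin[w] - 1L) * bs,
      end2 = tssBin[w] * bs, score = stats::runif(1, 2, 5), qvalue = 0.01)
  }
  loops <- do.call(rbind, loops)

  # variants: effect = destroy the max-information position of a planted
  # site; neutral = motif-free bin, any base change
  icPos <- vapply(tfNames, function(nm) which.max(apply(pwms[[nm]], 1, max)),
                  1L)
  eff <- list()
  pick <- sample(nWin, min(config$nEffectVariants, nWin))
  for (w in pick) {
    s0 <- siteStarts[[w]][1]
    r <- regOfWindow[w]
    pos0 <- s0 + icPos[r] - 1L
    refB <- substr(genomeStr, pos0 + 1L, pos0 + 1L)
    worst <- bases[which.min(pwms[[r]][icPos[r], ])]
    if (worst == refB) worst <- setdiff(bases, refB)[1]
    eff[[length(eff) + 1L]] <- data.frame(
      pos0 = pos0, ref = refB, alt = worst, kind = "effect",
      window = w, bin = binIndexOf(region, pos0))
  }
  # "motif-free" for the neutral class: no planted site, and chance-match
  # background in the lower half (under 0-floored log-odds scanning of a
  # random genome, literally zero-score bins are vanishingly rare)
  cand <- setdiff(seq_len(nb), c(unlist(elementBins), tssBin))
  motifFreeBins <- cand[rowSums(motif)[cand] <= stats::median(rowSums(motif)[cand])]
  neu <- list()
  for (b in sample(motifFreeBins, min(config$nNeutralVariants,
                                      length(motifFreeBins)))) {
    pos0 <- (b - 1L) * bs + sample.int(bs, 1L) - 1L
    refB <- substr(genomeStr, pos0 + 1L, pos0 + 1L)
    neu[[length(neu) + 1L]] <- data.frame(
      pos0 = pos0, ref = refB, alt = sample(setdiff(bases, refB), 1L),
      kind = "neutral", window = (b - 1L) %/% binsPerWin + 1L, bin = b)
  }
  variants <- rbind(do.call(rbind, eff), do.call(rbind, neu))

  truth <- list(
    chrom = "chrSim", genomeLength = L, binSize = bs,
    windowSize = config$windowSize, nWindows = nWin,
    regulatorOfWindow = tfNames[regOfWindow],
    classOfContext = classOfContext,
    elementBins = elementBins, tssBin = tssBin,
    plantedRegulators = tfNames[seq_len(config$nPlantedRegulators)],
    signalWeights = W,
    variants = variants)

  sim <- structure(list(genome = genomeStr, pwms = pwms, expression = expr,
                        signals = st, noiseFree = noiseFree, motif = motif,
                        loops = loops, variants = variants, truth = truth,
                        region = region, config = config),
                   class = "regulomeSim")
  if (!is.null(dir)) writeSim(sim, dir)
  sim
}

#' @describeIn simulateRegulome brief summary.
#' @param x a \code{regulomeSim}.
#' @param ... unused.
#' @export
print.regulomeSim <- function(x, ...) {
  cat(sprintf(paste0("regulomeSim: %d bp genome, %d windows, %d TFs ",
                     "(%d planted), %d contexts, %d signals, %d variants\n"),
              x$config$genomeLength, x$truth$nWindows, x$config$nTFs,
              x$config$nPlantedRegulators, x$config$nContexts,
              length(x$config$signals), nrow(x$variants)))
  invisible(x)
}

#' Write all simulated inputs in pipeline formats
#'
#' FASTA genome, window BED, expression TSV, signal-tensor container,
#' BEDPE loops, VCF variants, and the truth JSON.
#'
#' @param sim a \code{regulomeSim}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(sim$genome)
  names(g) <- sim$truth$chrom
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"))
  ws <- sim$config$windowSize
  windows <- GenomicRanges::GRanges(sim$truth$chrom,
    IRanges::IRanges(start = (seq_len(sim$truth$nWindows) - 1L) * ws + 1L,
                     width = ws),
    name = sprintf("window%03d", seq_len(sim$truth$nWindows)))
  writeBedRegions(windows, file.path(dir, "windows.bed"))
  utils::write.table(data.frame(gene = colnames(sim$expression),
                                t(sim$expression), check.names = FALSE),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeSignalTensor(sim$signals, file.path(dir, "signals.tsv"))
  bedpe <- data.frame(sim$loops[, c("chrom1", "start1", "end1", "chrom2",
                                    "start2", "end2")],
                      name = sprintf("loop%04d", seq_len(nrow(sim$loops))),
                      score = sim$loops$score, qvalue = sim$loops$qvalue)
  utils::write.table(bedpe, file.path(dir, "loops.bedpe"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writePWMs(sim$pwms, file.path(dir, "motifs.txt"))
  v <- sim$variants
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", sim$truth$chrom,
                   sim$config$genomeLength),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tKIND=%s", sim$truth$chrom,
                   v$pos0 + 1L, sprintf("var%03d", seq_len(nrow(v))),
                   v$ref, v$alt, v$kind))
  writeLines(vcf, file.path(dir, "variants.vcf"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Expected relationships from the truth record alone
#'
#' The recovery-test keys: which TF should top the importance ranking in
#' each window, which (element bin, TSS bin) pairs are true contacts, and
#' which variants are expected to have an effect.
#'
#' @param truth the \code{truth} list of a \code{regulomeSim} (or the
#'   parsed truth JSON).
#' @return list with \code{topTF} (per window), \code{truePairs}
#'   (data.frame window, elementBin, tssBin) and \code{variantEffects}
#'   (data.frame id/kind/expectedEffect).
#' @export
oracleScores <- function(truth) {
  pairs <- do.call(rbind, lapply(seq_len(truth$nWindows), function(w)
    data.frame(window = w, elementBin = unlist(truth$elementBins[[w]]),
               tssBin = truth$tssBin[w])))
  v <- as.data.frame(truth$variants)
  list(topTF = truth$regulatorOfWindow,
       truePairs = pairs,
       variantEffects = data.frame(kind = v$kind,
                                   expectedEffect = as.numeric(v$kind == "effect")))
}

#' Model-ready training instances from a simulation
#'
#' Builds one \code{\link{trainInstance}} per (window, context) pair:
#' one-hot window sequence, combined TF features for the context, target
#' signals (noisy by default), availability from the mask, and the
#' window-local planted-contact matrix.
#'
#' @param sim a \code{regulomeSim}.
#' @param contexts context names to include (default all).
#' @param windows window indices to include (default all).
#' @param noiseFree use the noise-free signals as targets.
#' @param withContacts attach per-window \code{ContactMatrix} objects.
#' @param shuffleExpression permutation of contexts applied to the
#'   expression rows before building TF inputs (mismatched conditioning
#'   control); default identity.
#' @return list of training instances.
#' @export
makeTrainingData <- function(sim, contexts = rownames(sim$expression),
                             windows = seq_len(sim$truth$nWindows),
                             noiseFree = FALSE, withContacts = TRUE,
                             shuffleExpression = NULL) {
  cfgW <- sim$config$windowSize
  bs <- sim$config$binSize
  binsPerWin <- cfgW %/% bs
  nTFpad <- padTFWidth(sim$config$nTFs)
  exprUse <- sim$expression
  if (!is.null(shuffleExpression))
    exprUse <- sim$expression[shuffleExpression, , drop = FALSE]
  rownames(exprUse) <- rownames(sim$expression)
  out <- list()
  for (w in windows) {
    w0 <- (w - 1L) * cfgW
    oh <- oneHotSequence(substr(sim$genome, w0 + 1L, w0 + cfgW))
    binIdx <- (w - 1L) * binsPerWin + seq_len(binsPerWin)
    motifW <- sim$motif[binIdx, , drop = FALSE]
    winRegion <- makeBins(sim$truth$chrom, w0, w0 + cfgW, bs)
    cm <- if (withContacts) buildContactMatrix(sim$loops, winRegion) else NULL
    for (cc in contexts) {
      ci <- match(cc, rownames(sim$expression))
      tfIn <- combineTF(motifW, exprUse[cc, ], nTFpad)
      target <- if (noiseFree)
        matrix(sim$noiseFree[ci, binIdx, ], binsPerWin,
               length(sim$config$signals))
      else signalValues(sim$signals, cc)[binIdx, , drop = FALSE]
      out[[length(out) + 1L]] <- trainInstance(
        onehot = oh, tfInput = tfIn, target = target,
        avail = availabilityMask(sim$signals)[ci, ],
        contacts = cm, context = cc,
        regionId = sprintf("window%03d", w))
    }
  }
  out
}
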