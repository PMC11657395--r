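test_that("GIS gradients match central finite differences", {
  cfg <- tinyConfig(nTF = 4L, nSignals = 2L)
  m <- tinyModel(cfg = cfg, seed = 70)
  set.seed(70)
  oh <- oneHotSequence(randomDna(512))
  motif <- matrix(runif(4 * 4), 4, 4,
                  dimnames = list(NULL, paste0("TF", 1:4)))
  motif[2, 1] <- 0; motif[, 3] <- 0      # TF3 never binds
  expr <- runif(4, 0.5, 2)
  g <- gisTable(m, oh, motif, expr, mode = "product")
  expect_equal(dim(g$gis), c(4L, 2L))
  expect_true(all(g$gis >= 0))
  expect_true(g$emptyZeta[3])
  expect_equal(unname(g$gis[3, ]), c(0, 0))   # empty zeta -> 0 with a flag
  # finite-difference oracle on the combined input entry (h = 1e-4)
  tfIn <- combineTF(motif, expr, cfg@nTFPadded)
  predAt <- function(tf) predictSignals(m, oh, tf)$pred
  h <- 1e-4
  for (t in c(1, 2)) for (k in 1:2) {
    z <- g$zeta[[t]]
    fd <- sapply(z, function(l) {
      up <- tfIn; up[l, t] <- up[l, t] + h
      dn <- tfIn; dn[l, t] <- dn[l, t] - h
      abs((predAt(up)[l, k] - predAt(dn)[l, k]) / (2 * h))
    })
    expect_equal(g$gis[t, k], mean(fd), tolerance = 1e-4,
                 label = sprintf("GIS[%d,%d]", t, k))
  }
})

test_that("expression-mode GIS chains through every bin", {
  cfg <- tinyConfig(nTF = 4L, nSignals = 2L)
  m <- tinyModel(cfg = cfg, seed = 71)
  set.seed(71)
  oh <- oneHotSequence(randomDna(512))
  motif <- matrix(runif(16), 4, 4, dimnames = list(NULL, paste0("TF", 1:4)))
  expr <- runif(4, 0.5, 2)
  g <- gisTable(m, oh, motif, expr, mode = "expression")
  # oracle: perturb the expression scalar, keeping the product structure
  h <- 1e-4
  t <- 2
  predAt <- function(e) predictSignals(m, oh,
    combineTF(motif, e, cfg@nTFPadded))$pred
  for (k in 1:2) {
    fd <- sapply(g$zeta[[t]], function(l) {
      up <- expr; up[t] <- up[t] + h
      dn <- expr; dn[t] <- dn[t] - h
      abs((predAt(up)[l, k] - predAt(dn)[l, k]) / (2 * h))
    })
    expect_equal(g$gis[t, k], mean(fd), tolerance = 1e-4)
  }
})

test_that("IGIS averages descending ranks with average ties", {
  # a TF first in all signals scores exactly 1
  g <- rbind(c(9, 8, 7), c(5, 4, 3), c(1, 2, 6))
  rownames(g) <- paste0("TF", 1:3)
  out <- igis(g)
  expect_equal(unname(out["TF1"]), 1)
  # two TFs tied everywhere in a 2-TF table both get 1.5
  tied <- rbind(c(2, 2), c(2, 2))
  expect_equal(unname(igis(tied)), c(1.5, 1.5))
  # random table vs brute-force rank loop
  set.seed(72)
  G <- matrix(runif(40), 5, 8)
  brute <- numeric(5)
  for (i in 1:5) {
    rs <- numeric(8)
    for (k in 1:8) rs[k] <- rank(-G[, k], ties.method = "average")[i]
    brute[i] <- mean(rs)
  }
  expect_equal(unname(igis(G)), brute, tolerance = 1e-12)
  # invariance under strictly monotone per-signal transforms
  G2 <- G; G2[, 3] <- exp(G2[, 3]); G2[, 5] <- G2[, 5]^3
  expect_equal(igis(G2), igis(G))
})

test_that("attention pair scores follow column and direct conventions", {
  # uniform attention: column score T * (1/T) = 1
  U <- matrix(1 / 8, 8, 8)
  expect_equal(attentionPairScore(U, 3, 5), 1)
  # identity attention: column 1, direct 0 for distinct bins
  I8 <- diag(8)
  expect_equal(attentionPairScore(I8, 4, 6), 1)
  expect_equal(attentionPairScore(I8, 4, 6, mode = "direct"), 0)
  # random toy equals explicit summation / lookup
  set.seed(73)
  A <- matrix(runif(64), 8, 8); A <- A / rowSums(A)
  expect_equal(attentionPairScore(A, 2, 5), sum(A[, 2]))
  expect_equal(attentionPairScore(A, 2, 5, mode = "direct"), A[2, 5])
  # conservation: column scores over all element bins sum to the token count
  expect_equal(sum(sapply(1:8, function(e) attentionPairScore(A, e, e))), 8,
               tolerance = 1e-12)
  # out-of-window pairs are rejected (64 kb at the published geometry)
  expect_error(attentionPairScore(A, 1, 8, binSize = 128e3 / 8,
                                  maxDistance = 64000), "exceeds")
  expect_error(attentionPairScore(A, 0, 3), "token range")
})

test_that("signal LOS is zero for identical alleles and antisymmetric", {
  cfg <- tinyConfig(nSignals = 3L)
  m <- tinyModel(cfg = cfg, seed = 74)
  set.seed(74)
  seq <- randomDna(512)
  ohRef <- oneHotSequence(seq)
  alt <- seq
  substr(alt, 257, 257) <- setdiff(c("A", "C", "G", "T"),
                                   substr(seq, 257, 257))[1]
  ohAlt <- oneHotSequence(alt)
  tfIn <- matrix(runif(4 * cfg@nTFPadded), 4, cfg@nTFPadded)
  expect_equal(losSignal(m, ohRef, ohRef, tfIn, 2), rep(0, 3))
  fwd <- losSignal(m, ohRef, ohAlt, tfIn, 2)
  rev <- losSignal(m, ohAlt, ohRef, tfIn, 2)
  expect_equal(fwd, -rev)                        # exact antisymmetry
  expect_true(all(is.finite(fwd)))
  # ref/alt differing at two loci is rejected; off-center variants warn
  alt2 <- alt
  substr(alt2, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(alt2, 10, 10))[1]
  expect_error(losSignal(m, ohRef, oneHotSequence(alt2), tfIn, 2),
               "variant locus only")
  expect_warning(losSignal(m, ohRef, ohAlt, tfIn, 4), "centered")
})

test_that("attention LOS sums absolute log-ratios over the 11-bin window", {
  set.seed(75)
  A <- matrix(runif(256), 16, 16); A <- A / rowSums(A)
  expect_equal(losAttention(A, A, 8), 0)
  # doubling exactly one bin's mass scores log 2
  B <- A; B[10, ] <- 2 * B[10, ]
  expect_equal(losAttention(A, B, 8, eps = 0), log(2), tolerance = 1e-12)
  # toy case equals a hand loop over the 11 offsets
  C <- matrix(runif(256), 16, 16); C <- C / rowSums(C)
  hand <- 0
  for (o in -5:5)
    hand <- hand + abs(log((rowSums(C)[8 + o] + 1e-6) /
                           (rowSums(A)[8 + o] + 1e-6)))
  expect_equal(losAttention(A, C, 8), hand, tolerance = 1e-12)
  # edge truncation flags and drops outside offsets
  expect_warning(v <- losAttention(A, C, 2), "truncated")
  expect_true(is.finite(v))
})

test_that("variant feature vectors concatenate 9 scores per context", {
  cfg <- tinyConfig(nSignals = 8L)
  m <- tinyModel(cfg = cfg, seed = 76)
  set.seed(76)
  seq <- randomDna(512)
  alt <- seq
  substr(alt, 250, 250) <- setdiff(c("A", "C", "G", "T"),
                                   substr(seq, 250, 250))[1]
  tfIns <- lapply(1:3, function(i)
    matrix(runif(4 * cfg@nTFPadded), 4, cfg@nTFPadded))
  names(tfIns) <- paste0("ctx", 1:3)
  # 4 tokens: the 11-bin attention neighborhood truncates with a warning
  fv <- suppressWarnings(
    variantFeatures(m, oneHotSequence(seq), oneHotSequence(alt), tfIns, 2))
  expect_length(fv, 9 * 3)            # (K + 1) per context; 252 at 28 contexts
  expect_true(all(is.finite(fv)))
  # permuting contexts permutes feature blocks
  fv2 <- suppressWarnings(
    variantFeatures(m, oneHotSequence(seq), oneHotSequence(alt),
                    tfIns[c(2, 3, 1)], 2))
  expect_equal(unname(fv2[1:9]), unname(fv[10:18]))
  expect_error(variantFeatures(m, oneHotSequence(seq), oneHotSequence(alt),
                               list(), 2), "at least one context")
})

test_that("percentile rank is 0 for a top score, 0.5 at the median, midrank on ties", {
  expect_equal(percentileRank(10, 1:9), 0)
  expect_equal(percentileRank(5, c(1:4, 6:9)), 0.5)
  expect_equal(percentileRank(5, c(4, 5, 6)), (1 + 0.5) / 3)
  expect_error(percentileRank(1, numeric(0)), "nonempty")
})

test_that("k-mer features count overlapping words and drop ambiguous ones", {
  v <- kmerFeatures("AAAAA", k = 5)
  expect_length(v, 1024L)             # 4^5
  expect_equal(unname(v["AAAAA"]), 1L)
  expect_equal(sum(v), 1L)
  # random 200-mer vs a dictionary-count oracle
  set.seed(77)
  s <- randomDna(200)
  v <- kmerFeatures(s, k = 5)
  words <- substring(s, 1:(200 - 4), 5:200)
  tab <- table(words)
  expect_equal(sum(v), 196L)
  for (w in sample(names(tab), 10))
    expect_equal(unname(v[w]), unname(as.integer(tab[w])))
  # N-containing k-mers are not counted
  vN <- kmerFeatures("AANAA", k = 5)
  expect_equal(sum(vN), 0L)
  expect_warning(vShort <- kmerFeatures("ACG", k = 5), "shorter")
  expect_equal(sum(vShort), 0L)
  expect_length(vShort, 1024L)
})
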