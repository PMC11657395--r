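test_that("masked MSE matches the brute-force double loop", {
  # 2 bins x 2 signals hand oracle
  pred <- rbind(c(1, 2), c(3, 4))
  targ <- rbind(c(0, 2), c(3, 2))
  expect_equal(maskedMSE(pred, targ, c(TRUE, TRUE)), (1 + 0 + 0 + 4) / 4)
  expect_equal(maskedMSE(pred, targ, c(TRUE, FALSE)), (1 + 0) / 2)
  expect_equal(maskedMSE(pred, pred, c(TRUE, TRUE)), 0)
  # differences only in masked cells contribute nothing
  targ2 <- pred; targ2[, 2] <- targ2[, 2] + 100
  expect_equal(maskedMSE(pred, targ2, c(TRUE, FALSE)), 0)
  # no available signal: contributes zero
  expect_equal(maskedMSE(pred, targ, c(FALSE, FALSE)), 0)
  expect_error(maskedMSE(pred, matrix(NaN, 2, 2), c(TRUE, TRUE)), "NaN")
  # random tensors vs explicit loops, 1e-10
  set.seed(31)
  for (rep in 1:5) {
    P <- matrix(rnorm(40), 8, 5)
    Y <- matrix(rnorm(40), 8, 5)
    av <- runif(5) > 0.4
    if (!any(av)) av[1] <- TRUE
    acc <- 0
    for (j in 1:8) {
      s <- 0
      for (k in which(av)) s <- s + (Y[j, k] - P[j, k])^2
      acc <- acc + s / sum(av)
    }
    expect_equal(maskedMSE(P, Y, av), acc / 8, tolerance = 1e-10)
  }
})

test_that("loop aggregation filters by q-value and row-normalizes", {
  region <- makeBins("chr1", 0, 1024, 128)
  loops <- data.frame(chrom1 = "chr1", start1 = c(0, 256), end1 = c(128, 384),
                      chrom2 = "chr1", start2 = c(640, 640),
                      end2 = c(768, 768),
                      score = c(3, 2), qvalue = c(1e-4, 0.01))
  cm <- buildContactMatrix(loops, region)
  H <- contactCounts(cm)
  # the q = 0.01 loop is dropped at the 0.001 threshold
  expect_equal(H[3, 6], 0)
  expect_equal(H[1, 6], 3); expect_equal(H[6, 1], 3)
  expect_equal(sum(H > 0), 2L)
  Hn <- normalizedContacts(cm)
  expect_equal(Hn[1, 6], 1)                       # unit mass at the partner
  expect_equal(Hn[6, 1], 1)
  expect_equal(validContactRows(cm), seq_len(8) %in% c(1, 6))
  expect_true(validObject(cm))
})

test_that("multi-loop aggregation matches a brute-force accumulation", {
  region <- makeBins("chr1", 0, 2048, 128)
  set.seed(32)
  n <- 12
  loops <- data.frame(chrom1 = "chr1",
                      start1 = sample(seq(0, 1792, 128), n, TRUE),
                      chrom2 = "chr1",
                      start2 = sample(seq(0, 1792, 128), n, TRUE),
                      score = runif(n, 1, 5),
                      qvalue = sample(c(1e-5, 0.05), n, TRUE))
  loops$end1 <- loops$start1 + 256   # anchors span two bins
  loops$end2 <- loops$start2 + 256
  H <- matrix(0, 16, 16)
  for (i in 1:n) {
    if (loops$qvalue[i] > 0.001) next
    for (a in (loops$start1[i] / 128 + 1):(loops$end1[i] / 128)) {
      for (b in (loops$start2[i] / 128 + 1):(loops$end2[i] / 128)) {
        H[a, b] <- H[a, b] + loops$score[i]
        H[b, a] <- H[b, a] + loops$score[i]
      }
    }
  }
  cm <- buildContactMatrix(loops, region)
  expect_equal(contactCounts(cm), H, tolerance = 1e-12)
})

test_that("BEDPE parsing surfaces malformed lines by number", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "loops.bedpe")
  writeLines(c("chr1\t0\t128\tchr1\t640\t768\tl1\t3\t1e-4",
               "chr1\t0\t128\tchr1"), p)
  expect_error(readLoops(p), "line 2")
  writeLines(c("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tcount\tfdr",
               "chr1\t0\t128\tchr1\t640\t768\tl1\t3\t1e-4"), p)
  lp <- readLoops(p, scoreCol = "count", qCol = "fdr")
  expect_equal(lp$score, 3)
  expect_equal(lp$qvalue, 1e-4)
})

test_that("contact-guidance loss is the row-cosine complement", {
  region <- makeBins("chr1", 0, 768, 128)
  H <- matrix(0, 6, 6); H[1, 4] <- H[4, 1] <- 2; H[2, 5] <- H[5, 2] <- 1
  Hn <- H / pmax(rowSums(H), 1)
  cm <- new("ContactMatrix", H = H, Hnorm = Hn, validRows = rowSums(H) > 0,
            resolution = 128)
  # attention rows proportional to contact rows -> loss 0
  A <- Hn * 0.5 + 0
  A[rowSums(Hn) == 0, ] <- 1 / 6
  expect_equal(contactGuidanceLoss(A, cm), 0, tolerance = 1e-12)
  # orthogonal rows -> loss 1
  B <- matrix(0, 6, 6); B[1, 2] <- 1; B[4, 5] <- 1; B[2, 1] <- 1; B[5, 1] <- 1
  expect_equal(contactGuidanceLoss(B, cm), 1)
  # random toy equals the explicit per-row cosine loop
  set.seed(33)
  R <- matrix(runif(36), 6, 6); R <- R / rowSums(R)
  acc <- c()
  for (r in which(rowSums(H) > 0))
    acc <- c(acc, sum(R[r, ] * Hn[r, ]) /
               (sqrt(sum(R[r, ]^2)) * sqrt(sum(Hn[r, ]^2))))
  expect_equal(contactGuidanceLoss(R, cm), 1 - mean(acc), tolerance = 1e-12)
  expect_gte(contactGuidanceLoss(R, cm), 0)
  expect_lte(contactGuidanceLoss(R, cm), 2)
  # no contacts at all: loss 0 with a warning
  empty <- new("ContactMatrix", H = H * 0, Hnorm = H * 0,
               validRows = rep(FALSE, 6), resolution = 128)
  expect_warning(l0 <- contactGuidanceLoss(R, empty), "no contact")
  expect_equal(l0, 0)
})

test_that("total loss composes MSE and guidance linearly in alpha", {
  pred <- rbind(c(1, 0), c(0, 1)); targ <- pred * 0
  avail <- c(TRUE, TRUE)
  H <- matrix(0, 2, 2); H[1, 2] <- H[2, 1] <- 1
  cm <- new("ContactMatrix", H = H, Hnorm = H, validRows = c(TRUE, TRUE),
            resolution = 128)
  A <- diag(2)   # orthogonal to H rows -> CSL = 1
  mse <- maskedMSE(pred, targ, avail)
  expect_equal(totalLoss(pred, targ, avail, alpha = 0), mse)
  expect_equal(totalLoss(pred, targ, avail, A, cm, alpha = 2), mse + 2)
  ls <- sapply(c(0, 0.5, 1, 2), function(a)
    totalLoss(pred, targ, avail, A, cm, alpha = a))
  expect_true(all(diff(ls) > 0))   # monotone in alpha when CSL > 0
})

test_that("guidance gradients reach attention weights even at an MSE optimum", {
  cfg <- tinyConfig()
  m <- tinyModel(cfg = cfg, seed = 40)
  inp <- tinyInputs(cfg, seed = 40)
  H <- matrix(0, 4, 4); H[1, 3] <- H[3, 1] <- 1
  Hn <- H / pmax(rowSums(H), 1)
  tape <- epicontext:::adTape()
  pn <- epicontext:::paramLeaves(tape, m@params)
  fw <- epicontext:::forwardTape(cfg, pn, inp$onehot, inp$tfInput, tape,
                                 wantAttention = TRUE)
  target <- epicontext:::adVal(fw$pred)   # pred == target: MSE stationary
  mseNode <- epicontext:::adMaskedMSE(fw$pred, target, rep(TRUE, cfg@nSignals))
  aAvg <- epicontext:::adMeanOf(unlist(fw$attn[cfg@nLayers], recursive = FALSE))
  csl <- epicontext:::adCosineRowsLoss(aAvg, Hn, rowSums(H) > 0)
  tot <- epicontext:::adAdd(mseNode, epicontext:::adScale(csl, 2))
  epicontext:::adBackward(tot)
  expect_gt(max(abs(pn$L1_h1_Wq$grad)), 0)
  expect_gt(max(abs(pn$L1_h1_Wk$grad)), 0)
  # the MSE part alone contributes no gradient
  epicontext:::adBackward(mseNode)
  expect_equal(max(abs(pn$L1_h1_Wq$grad)), 0)
})

test_that("training is seeded, decreases the loss, and can overfit one instance", {
  cfg <- tinyConfig()
  set.seed(50)
  inst <- trainInstance(
    onehot = oneHotSequence(randomDna(512)),
    tfInput = matrix(runif(4 * cfg@nTFPadded), 4, cfg@nTFPadded),
    target = matrix(rnorm(4 * cfg@nSignals, sd = 0.5), 4, cfg@nSignals),
    avail = rep(TRUE, cfg@nSignals))
  expect_error(trainModel(tinyModel(cfg = cfg), list(),
                          trainConfig(seed = 1)), "empty")
  tc <- trainConfig(steps = 400L, batchSize = 1L, learningRate = 5e-3,
                    alpha = 0, seed = 7)
  fit <- trainModel(tinyModel(cfg = cfg, seed = 7), list(inst), tc)
  expect_lt(tail(fit$history$mse, 1), 1e-3)   # single-instance overfit
  expect_lt(mean(tail(fit$history$loss, 50)),
            mean(head(fit$history$loss, 50)))
  # same seed, same result; different seed, different result
  tc2 <- trainConfig(steps = 40L, batchSize = 1L, learningRate = 5e-3,
                     alpha = 0, seed = 11)
  f1 <- trainModel(tinyModel(cfg = cfg, seed = 2), list(inst), tc2)
  f2 <- trainModel(tinyModel(cfg = cfg, seed = 2), list(inst), tc2)
  expect_identical(tail(f1$history$loss, 1), tail(f2$history$loss, 1))
  expect_identical(f1$model@params, f2$model@params)
})

test_that("anchor-bin selection uses the midpoint rule and pair features concatenate", {
  region <- makeBins("chr1", 0, 4096, 128)
  # anchor [256, 640): bins 3,4,5 have midpoints 320,448,576 inside
  expect_equal(anchorBins(region, 256, 640), 3:5)
  expect_equal(anchorBins(region, 256, 576), 3:4)   # 576 excluded, half-open
  expect_error(anchorBins(region, -5, 640), "outside")
  hidden <- matrix(seq_len(32 * 5), 32, 5)
  f <- pairFeatures(hidden, 3:5, 10:12)
  expect_length(f, 6 * 5)    # toy: 3+3 anchor bins x width 5
  expect_equal(f[1:5], hidden[3, ])
  expect_equal(f[26:30], hidden[12, ])
})

test_that("the fine-tuned pair head separates separable classes", {
  set.seed(60)
  n <- 80
  mu <- c(rep(1.5, 10), rep(-1.5, 10))
  X <- rbind(matrix(rnorm(n / 2 * 20, mean = mu), n / 2, 20, byrow = TRUE),
             matrix(rnorm(n / 2 * 20, mean = -mu), n / 2, 20, byrow = TRUE))
  y <- rep(c(1, 0), each = n / 2)
  head <- finetuneEP(X, y, hidden = 16L, steps = 150L, seed = 3)
  p <- predict(head, X)
  expect_gt(binaryMetrics(y, p)$auroc, 0.9)
  expect_true(all(p > 0 & p < 1))
})
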