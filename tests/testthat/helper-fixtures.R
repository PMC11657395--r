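# Shared fixture builders. Everything is generated in code; tiny scales so
# each file stays fast.

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Smallest workable architecture: 512-bp window -> 4 tokens of 128 bp.
tinyConfig <- function(nSignals = 3L, nLayers = 1L, nHeads = 2L, nTF = 4L) {
  modelConfig("toy", inputLength = 512, binSize = 128, nTF = nTF,
              nSignals = nSignals, seqChannels = 4L,
              convChannels = c(4L, 4L, 4L, 4L, 4L),
              nHeads = nHeads, nLayers = nLayers)
}

tinyModel <- function(seed = 1L, cfg = tinyConfig()) initModel(cfg, seed = seed)

tinyInputs <- function(cfg, seed = 1L) {
  set.seed(seed)
  oh <- oneHotSequence(randomDna(cfg@inputLength))
  tfIn <- matrix(runif(nTokens(cfg) * cfg@nTFPadded), nTokens(cfg),
                 cfg@nTFPadded)
  list(onehot = oh, tfInput = tfIn)
}

# Brute-force PWM scan: explicit offset loop, independent of the
# vectorized implementation.
bruteMaxScore <- function(pwm, seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  w <- nrow(pwm)
  if (length(ch) < w) return(0)
  best <- -Inf
  for (o in 1:(length(ch) - w + 1)) {
    s <- 0
    for (t in 1:w) {
      j <- match(ch[o + t - 1], c("A", "C", "G", "T"))
      s <- s + if (is.na(j)) 0 else pwm[t, j]
    }
    best <- max(best, s)
  }
  max(0, best)
}

# Finite-difference loss gradient for one scalar parameter entry.
fdGrad <- function(lossFn, params, name, idx, h = 1e-5) {
  p2 <- params; p2[[name]][idx] <- p2[[name]][idx] + h
  p3 <- params; p3[[name]][idx] <- p3[[name]][idx] - h
  (lossFn(p2) - lossFn(p3)) / (2 * h)
}
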