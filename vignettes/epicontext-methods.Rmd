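---
title: "epicontext: model, training, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epicontext: model, training, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epicontext)
```

# The model

`epicontext` predicts binned epigenomic signals from two inputs: the DNA
sequence of a window and a description of the cellular context given as
transcription-factor (TF) expression. Because the context enters as an
ordinary input vector — never as a one-hot context identity — a trained
model extrapolates to contexts it has not seen, which is the point of the
design.

A window of `L` bp is cut into `L/N` bins of `N` bp; each bin becomes one
transformer token. The token embedding concatenates:

1. a sequence embedding from five convolution blocks (convolution, ReLU,
   max-pool), whose pool factors multiply to `N` so that `L x 4` one-hot
   input becomes `L/N x C`;
2. a TF feature of width `n_TF` (padded to an even width; 711 TFs pad to
   712 at the published scale): per bin, the maximal PWM log-odds match
   score of each TF's motif, floored at 0, multiplied by the context's
   quantile-normalized log1p TPM for that TF.

A learned absolute position embedding (`tokens x d_model`) is added once.
`N_t` post-norm encoder layers follow, each multi-head self-attention
(`softmax(QK^T/sqrt(d_k)) V`, learned `W_Q, W_K, W_V` per head, concat,
`W_O`) then a GELU feed-forward, both with add & norm. A linear head maps
each token to `K` signals; a sigmoid is appended for the classification
design. Attention matrices of every layer and head can be captured
(`AttentionSummary`), both for interpretation and for the contact-guidance
loss.

## Losses

Tracks are missing for many (context, signal) pairs in real compendia, so
the training loss averages only over the available signal set `B_i` of
context `i`:

    L = (1/J) sum_j (1/|B_i|) sum_k (y_ijk - yhat_ijk)^2 * I(k in B_i)

An instance with `|B_i| = 0` contributes zero and no gradient. Missing
values are carried as a mask plus zeros, never as sentinels, so they cannot
leak into losses.

With chromatin-contact data, loops passing a stringent q-value filter
(`q <= 0.001`) are aggregated symmetrically onto every overlapped bin pair
to form `H`, which is row-normalized to `H~` (all-zero rows stay zero and
are flagged). The guidance term is a cosine-similarity loss between rows of
`H~` and the head-averaged attention of the last encoder layer(s):

    CSL = 1 - mean over valid rows of cos(A~_row, H~_row)

added with weight `alpha` (default 2; `alpha = 0` reduces the total loss
exactly to the masked MSE). Three choices here were genuinely open and are
resolved as follows:

- *Sign/shape of the "cosine similarity loss"*: implemented as
  `1 - mean cosine`, so 0 is perfect alignment and lower is better.
- *Zero rows of `H~`*: excluded from the loss. Absent loops are missing
  data, not observed non-interaction.
- *Which attention feeds the loss*: the head average over the last layer
  (`lastNLayers = 1`, configurable), reading the plural-ambiguous "last
  layers" minimally.

## Optimization

Adam (defaults: learning rate 5e-5, batch 10 — the published recipe) over
(context, region) instances; each step builds one autodiff tape over its
minibatch, averages the per-instance losses, backpropagates and updates.
Training is bit-deterministic given the seed (the seed is mandatory). A
non-finite loss aborts and returns the last finite-loss parameters. The
desk-scale runs in the test suite use lr 2e-3, batch 4 and 600 steps — at
a few thousand parameters the published step size would be needlessly slow,
and 600 steps sits inside the 500–2000 range the recovery properties are
stated for.

## The autodiff engine

No deep-learning framework exists in this R environment, so the package
carries a ~250-line reverse-mode tape (`R/autodiff.R`): matmul (with
transposed variants), broadcast add, elementwise ops, ReLU/GELU/sigmoid,
row softmax, row layer-norm, same-padded conv1d by im2col, non-overlapping
max-pool, and fused loss ops (masked MSE, row-cosine contact loss, BCE).
Every op's gradient, and the full composed model, is checked against
central finite differences in the tests (relative error ~1e-9 at h = 1e-5).
This engine also powers the interpretation machinery: gradient importance
scores are exact input gradients, not approximations.

# Interpretation machinery

**GIS/IGIS.** For a TF `t`, `zeta_t` is the set of bins with positive motif
score. `GIS_tk` is the mean over `l in zeta_t` of `|d yhat_lk / d tf_t|`.
The differentiation target is configurable because the method is used both
ways: `"product"` differentiates the combined motif-x-expression entry of
the output bin; `"expression"` differentiates the scalar TPM entry, whose
gradient chains through every bin of the window. `IGIS` ranks TFs within
each signal (rank 1 = largest, ties averaged) and averages ranks over the
`K` signals. An empty `zeta` yields GIS 0 with a flag.

**Variant effects (LOS).** A forward pass on the reference and the
alternative window gives per-signal natural-log ratios at the variant's
bin; outputs are clamped at 0 and floored at `eps = 1e-6` so ratios stay
finite (the regression head can go negative; the published outputs are
non-negative normalized counts, so the clamp is the faithful reading).
Ratios are signed — direction of change is information. The attention
score sums `|log ratio|` of per-bin attention mass over offsets −5..+5
(11 bins, following the printed formula rather than the "10 bins" prose;
the half-width is configurable). Attention "mass" defaults to row sums,
with column or row+column as options. Concatenating `K` signal scores plus
the attention score per context gives the variant feature vector — 9 per
context, 252 for the published 28 contexts. Important: the TF features of
the alternative allele should be recomputed from the alternative sequence
(`tfInputAlt`), since a motif-destroying SNV acts mostly through the
binding-score channel; passing only the sequence change misses most of the
effect.

**Element–gene attention scores** use the attention matrix averaged over
all layers and heads; the default score for a pair is the total attention
the element's token receives (column sum), with the direct
element-to-TSS entry as the published alternative; pairs farther apart
than half the window (64 kb at published scale) are rejected. Distance
stratification uses half-open bands 0–20/20–40/40–64 kb, and negatives are
mirrored to the opposite side of the TSS at identical distance (or sampled
distance-matched from a pool).

**Prioritization.** `percentileRank(score, background)` is the fraction of
background scores exceeding the score, with midrank ties — 0 is best, and
exchangeable draws average 0.5, which the acceptance script verifies by
Monte Carlo.

# The synthetic world

`simulateRegulome()` generates everything the pipeline ingests, with
planted structure whose recovery the acceptance tests measure. Defaults
(the "stated world") are: 512-kb genome, 128-bp bins, 4096-bp model
windows, 8 TFs of which 2 are planted regulators, 6 contexts, the default
8-signal panel, masking rate 0.25.

- Each window is driven by exactly one planted regulator, alternating;
  2 consensus sites per window are written into random non-TSS bins.
- Contexts alternate which regulator is active: active expression
  ~ U(1.5, 2.5), inactive ~ U(0, 0.1), bystander TFs ~ U(0.5, 1.5). Context
  identity is therefore carried entirely by expression, and conditioning a
  window on the wrong class's expression predicts the wrong spatial
  pattern — the negative control the acceptance suite exploits.
- Signals follow `softplus(sum_t W[t,k] motif[j,t] expr[c,t])`, smoothed
  over ±1 bin (fragment-size blurring), plus Gaussian noise (sd 0.05)
  clamped at 0. `signalWeight = 0.15` puts signals on a realistic
  log1p-count scale (peaks ~2–4); noise sd 0.05 is a few percent of peak
  height, a modest measurement-noise level.
- Loops connect every planted element bin to the window's designated TSS
  bin at q = 1e-4, plus one decoy loop per window at q = 0.01 that the
  0.001 filter must remove.
- Effect variants flip the highest-information position of a planted site
  to the PWM's worst base; neutral variants land in bins with no planted
  site and below-median chance-match background. (Under 0-floored log-odds
  scanning of a random genome, literally motif-free bins essentially do
  not exist — every 128-bp bin contains some positive-scoring offset for
  some sharp 8-mer PWM — so "motif-free" is implemented as
  "no planted site, low background".)

What a green recovery test does establish: the implementation can learn the
multiplicative sequence-x-expression rule, generalize it to unseen
contexts, align attention to planted contacts when asked, and expose
planted drivers and variant effects through its attribution scores. What it
does not establish: performance on real chromatin data, where signals are
not a clean function of motif-x-expression, contexts are correlated, and
contacts are distance-decaying rather than planted — published-scale
claims are out of scope here.

# Numerical and design choices

- **One-hot basis**: the standard A=[1,0,0,0], C=[0,1,0,0], G=[0,0,1,0],
  T=[0,0,0,1] (the printed legend lists A and T identically, which is
  self-contradictory; C and G match the printed rows). `N` is a zero row.
- **Coordinates**: 0-based half-open genomically (BED); 1-based bin/token
  indices inside R; VCF positions converted on ingest.
- **Strand**: forward-only scanning by default, `bothStrands` optional.
- **Motif scanning**: log-odds PWM scores floored at 0 stand in for the
  external motif tool's "reported binding"; the tool's normalization and
  threshold are unpublished, so the floor is a documented substitution.
- **Quantile normalization**: classical mean-of-sorted-columns reference
  with average-tie handling, via limma.
- **Binarization**: strictly greater than 30 raw counts, applied to raw
  (not normalized) counts as the text states.
- **Conv kernel 9 (toy: 5), FFN width 4x d_model, GELU in the FFN, pool
  factors [2,2,2,4,4]**: the publication does not state them; these are
  standard encoder sizings, all configurable. The published 71.3M total
  parameter count is therefore not reproducible and `countParameters()`
  reports whatever the configuration implies.
- **Fine-tuning anchors**: bins whose midpoint falls inside the anchor;
  the published 76,472-dim feature (79 bins x 968) is not derivable from
  2 x 5000/128 bins, so the rule is configurable and the discrepancy
  acknowledged.
- **Checkpoints and containers**: single-file JSON checkpoint (config +
  weights at full double precision); the signal tensor container is a
  plain-text block format with a JSON header at %.17g, round-tripping
  bit-exactly — this environment has no R HDF5 bindings, and text keeps
  the artifact fully inspectable.
- **Loss bookkeeping**: per instance, mean over bins and over available
  signals; minibatch = mean over instances (reading the loss's ambiguous
  outer index as the per-instance context).

# Known limitations

- Pure-R training: ~15–40 ms per desk-scale step; published-scale training
  is architecturally supported (the config validates and counts) but
  computationally out of reach by design.
- Single window per forward pass; no batching across windows inside one
  tape call other than the training loop's accumulation.
- BEDPE ingestion is a minimal reader (6 coordinate columns + configurable
  score/q-value columns), not a full spec parser.
- The synthetic genome has no GC structure, repeats, or distance-dependent
  contact background; recovery difficulty is therefore optimistic relative
  to real data.
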