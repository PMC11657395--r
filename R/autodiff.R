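# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape is an environment holding nodes in creation order; a node is an
# environment with the forward value, parent nodes, and a backward closure
# mapping the output gradient to per-parent gradients. Define-by-run: the
# model forward pass builds a fresh tape every step. This is deliberately
# small — only the ops the network needs — and every op's gradient is
# checked against central finite differences in the test suite.

adTape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

adNode <- function(tape, value, parents = NULL, backward = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  node <- new.env(parent = emptyenv())
  node$id <- n
  node$tape <- tape
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

# Leaf with gradient tracking (parameters and differentiable inputs).
adLeaf <- function(tape, value) adNode(tape, value)

adIsNode <- function(x) is.environment(x)
adVal <- function(x) if (is.environment(x)) x$value else x
adTapeOf <- function(...) {
  for (x in list(...)) if (is.environment(x)) return(x$tape)
  stop("at least one argument must be a tape node")
}

adAccum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Backpropagate from `node`, seeding with `seed` (1 for a scalar loss, or a
# matrix shaped like node$value to extract a Jacobian row). Clears all grads
# on the tape first, so repeated calls on one tape are independent.
adBackward <- function(node, seed = 1) {
  tape <- node$tape
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  v <- node$value
  node$grad <- if (is.matrix(v) && !is.matrix(seed)) matrix(seed, nrow(v), ncol(v)) else seed
  for (i in seq.int(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps))
      if (adIsNode(ps[[j]]) && !is.null(gs[[j]])) adAccum(ps[[j]], gs[[j]])
  }
  invisible(NULL)
}

## ---- primitive ops ----

# C = op(A) %*% op(B); either argument may be a constant matrix.
adMatmul <- function(a, b, transposeB = FALSE) {
  tape <- adTapeOf(a, b)
  av <- adVal(a); bv <- adVal(b)
  v <- if (transposeB) av %*% t(bv) else av %*% bv
  adNode(tape, v, parents = list(a, b), backward = function(g) {
    ga <- if (adIsNode(a)) { if (transposeB) g %*% bv else g %*% t(bv) }
    gb <- if (adIsNode(b)) { if (transposeB) t(g) %*% av else t(av) %*% g }
    list(ga, gb)
  })
}

# Elementwise sum; b may be a length-ncol(a) vector broadcast over rows.
adAdd <- function(a, b) {
  tape <- adTapeOf(a, b)
  av <- adVal(a); bv <- adVal(b)
  broadcast <- is.matrix(av) && !is.matrix(bv) && length(bv) == ncol(av)
  v <- if (broadcast) av + matrix(bv, nrow(av), ncol(av), byrow = TRUE) else av + bv
  adNode(tape, v, parents = list(a, b), backward = function(g) {
    ga <- if (adIsNode(a)) g
    gb <- if (adIsNode(b)) { if (broadcast) colSums(g) else g }
    list(ga, gb)
  })
}

adSub <- function(a, b) {
  tape <- adTapeOf(a, b)
  adNode(tape, adVal(a) - adVal(b), parents = list(a, b), backward = function(g)
    list(if (adIsNode(a)) g, if (adIsNode(b)) -g))
}

# Elementwise product; b may be a scalar or same-shape matrix (node or const).
adMul <- function(a, b) {
  tape <- adTapeOf(a, b)
  av <- adVal(a); bv <- adVal(b)
  adNode(tape, av * bv, parents = list(a, b), backward = function(g)
    list(if (adIsNode(a)) g * bv,
         if (adIsNode(b)) { gb <- g * av; if (length(bv) == 1) sum(gb) else gb }))
}

adScale <- function(a, s) {
  adNode(a$tape, adVal(a) * s, parents = list(a), backward = function(g) list(g * s))
}

adReLU <- function(a) {
  av <- adVal(a)
  m <- av > 0
  adNode(a$tape, av * m, parents = list(a), backward = function(g) list(g * m))
}

adGELU <- function(a) {
  av <- adVal(a)
  p <- stats::pnorm(av)
  adNode(a$tape, av * p, parents = list(a),
         backward = function(g) list(g * (p + av * stats::dnorm(av))))
}

adSigmoid <- function(a) {
  s <- 1 / (1 + exp(-adVal(a)))
  adNode(a$tape, s, parents = list(a), backward = function(g) list(g * s * (1 - s)))
}

# Row-wise softmax (each row of the value sums to 1).
adSoftmaxRows <- function(a) {
  av <- adVal(a)
  m <- av - apply(av, 1, max)
  e <- exp(m)
  y <- e / rowSums(e)
  adNode(a$tape, y, parents = list(a), backward = function(g)
    list((g - rowSums(g * y)) * y))
}

# Row-wise layer normalization with learned gain/bias vectors.
adLayerNormRows <- function(a, gamma, beta, eps = 1e-5) {
  tape <- adTapeOf(a, gamma, beta)
  x <- adVal(a); gv <- adVal(gamma); bv <- adVal(beta)
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd
  n <- nrow(x); k <- ncol(x)
  v <- xhat * matrix(gv, n, k, byrow = TRUE) + matrix(bv, n, k, byrow = TRUE)
  adNode(tape, v, parents = list(a, gamma, beta), backward = function(g) {
    dxhat <- g * matrix(gv, n, k, byrow = TRUE)
    ga <- if (adIsNode(a))
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    list(ga,
         if (adIsNode(gamma)) colSums(g * xhat),
         if (adIsNode(beta)) colSums(g))
  })
}

adCbind <- function(a, b) {
  tape <- adTapeOf(a, b)
  av <- adVal(a); bv <- adVal(b)
  ka <- ncol(av)
  adNode(tape, cbind(av, bv), parents = list(a, b), backward = function(g)
    list(if (adIsNode(a)) g[, seq_len(ka), drop = FALSE],
         if (adIsNode(b)) g[, -seq_len(ka), drop = FALSE]))
}

adSum <- function(a) {
  av <- adVal(a)
  adNode(a$tape, sum(av), parents = list(a), backward = function(g)
    list(if (is.matrix(av)) matrix(g, nrow(av), ncol(av)) else rep(g, length(av))))
}

adMeanOf <- function(nodes) {
  tot <- nodes[[1]]
  for (i in seq_along(nodes)[-1]) tot <- adAdd(tot, nodes[[i]])
  adScale(tot, 1 / length(nodes))
}

# Same-padded 1-d convolution along rows. x: L x Cin (node or const),
# W: (kernel*Cin) x Cout, b: length Cout. im2col formulation.
adConv1d <- function(x, W, b, kernel) {
  tape <- adTapeOf(x, W, b)
  xv <- adVal(x); Wv <- adVal(W); bv <- adVal(b)
  L <- nrow(xv); cin <- ncol(xv)
  padL <- (kernel - 1L) %/% 2L
  padR <- kernel - 1L - padL
  xp <- matrix(0, L + kernel - 1L, cin)
  xp[padL + seq_len(L), ] <- xv
  xcol <- matrix(0, L, kernel * cin)
  for (t in seq_len(kernel))
    xcol[, (t - 1L) * cin + seq_len(cin)] <- xp[t - 1L + seq_len(L), , drop = FALSE]
  v <- xcol %*% Wv
  v <- v + matrix(bv, L, ncol(Wv), byrow = TRUE)
  adNode(tape, v, parents = list(x, W, b), backward = function(g) {
    gx <- NULL
    if (adIsNode(x)) {
      gcol <- g %*% t(Wv)
      gxp <- matrix(0, L + kernel - 1L, cin)
      for (t in seq_len(kernel)) {
        idx <- t - 1L + seq_len(L)
        gxp[idx, ] <- gxp[idx, ] + gcol[, (t - 1L) * cin + seq_len(cin), drop = FALSE]
      }
      gx <- gxp[padL + seq_len(L), , drop = FALSE]
    }
    list(gx,
         if (adIsNode(W)) crossprod(xcol, g),
         if (adIsNode(b)) colSums(g))
  })
}

# Non-overlapping max pooling by factor p along rows: L x C -> (L/p) x C.
adMaxPool <- function(a, p) {
  av <- adVal(a)
  L <- nrow(av); C <- ncol(av)
  stopifnot(L %% p == 0)
  Lp <- L %/% p
  xm <- matrix(av, nrow = p)                    # p x (Lp*C), column-major
  arg <- max.col(t(xm), ties.method = "first")  # per pooled cell
  lin <- (seq_along(arg) - 1L) * p + arg        # linear index into av
  v <- matrix(av[lin], Lp, C)
  adNode(a$tape, v, parents = list(a), backward = function(g) {
    gx <- matrix(0, L, C)
    gx[lin] <- as.vector(g)
    list(gx)
  })
}

## ---- fused loss ops ----

# Masked multi-task MSE for one instance: mean over bins of the mean squared
# error over available signals. avail is a logical K-vector; an instance
# with no available signal contributes value 0 and no gradient.
adMaskedMSE <- function(pred, target, avail) {
  pv <- adVal(pred)
  nb <- sum(avail)
  if (nb == 0L)
    return(adNode(pred$tape, 0, parents = list(pred), backward = function(g) list(NULL)))
  M <- matrix(as.numeric(avail), nrow(pv), length(avail), byrow = TRUE)
  D <- (pv - target) * M
  denom <- nrow(pv) * nb
  adNode(pred$tape, sum(D * D) / denom, parents = list(pred),
         backward = function(g) list(2 * g * D / denom))
}

# Contact-guidance loss: 1 - mean over valid rows of cosine(att row, H~ row).
adCosineRowsLoss <- function(att, Hn, validRows) {
  av <- adVal(att)
  rows <- which(validRows)
  if (length(rows) == 0L)
    return(adNode(att$tape, 0, parents = list(att), backward = function(g) list(NULL)))
  A <- av[rows, , drop = FALSE]
  H <- Hn[rows, , drop = FALSE]
  na <- sqrt(rowSums(A * A)); nh <- sqrt(rowSums(H * H))
  na <- pmax(na, 1e-12)
  cosr <- rowSums(A * H) / (na * nh)
  m <- length(rows)
  adNode(att$tape, 1 - mean(cosr), parents = list(att), backward = function(g) {
    gA <- -(H / (na * nh) - cosr * A / (na * na)) / m
    gx <- matrix(0, nrow(av), ncol(av))
    gx[rows, ] <- gA * g
    list(gx)
  })
}

# Numerically stable binary cross-entropy on logits (mean over elements).
adBCEWithLogits <- function(logits, labels) {
  z <- adVal(logits)
  n <- length(z)
  v <- mean(pmax(z, 0) - z * labels + log1p(exp(-abs(z))))
  s <- 1 / (1 + exp(-z))
  adNode(logits$tape, v, parents = list(logits),
         backward = function(g) list(g * (s - labels) / n))
}
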