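# Internal neural-network primitives.
#
# Batched feature maps are stored as dense matrices with B*L rows and C
# columns, sequence-major: the row of (sequence b, position t) is
# (b-1)*L + t. Every forward returns a cache sufficient for its backward;
# backwards return gradients in the same shapes as their inputs/params.
# Everything is double precision base R so a fixed seed gives
# bit-reproducible runs.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmaxRows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)                      # x - m recycles down columns
  e / rowSums(e)
}

.relu <- function(x) (x > 0) * x

# Glorot/uniform initialization for a fanIn x fanOut matrix.
.glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

## ---- dense (position-wise fully connected) --------------------------------

dense_fwd <- function(X, W, b) {
  Z <- X %*% W
  Z <- sweep(Z, 2L, b, "+")
  list(Y = Z, X = X)
}

dense_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

## ---- 1-D convolution (same padding, dilation) -----------------------------

# Same-padded dilated convolution, computed as a sum over taps of
# shifted matrix products on a zero-padded copy of the input (each
# sequence padded with `span` zero rows on both sides), so every tap is
# one row gather, one GEMM and one full-matrix add — no im2col buffer
# and no indexed read-modify-write. Index vectors are memoized per
# (L, B, kernel, dilation) geometry.
.convIndexCache <- new.env(parent = emptyenv())

conv_geometry <- function(L, B, kernel, dilation) {
  key <- paste(L, B, kernel, dilation, sep = "_")
  g <- .convIndexCache[[key]]
  if (!is.null(g)) return(g)
  span <- (kernel - 1L) * dilation
  left <- span %/% 2L
  Lp <- L + 2L * span                     # padded per-sequence length
  basePad <- (0:(B - 1L)) * Lp
  # padded rows holding the real positions 1..L of every sequence
  center <- rep.int(basePad, rep.int(L, B)) + span + rep.int(1:L, B)
  # gather indices for tap j: padded row of position t + offset
  offsets <- (seq_len(kernel) - 1L) * dilation - left
  taps <- lapply(offsets, function(o) center + o)
  g <- list(span = span, Lp = Lp, center = center, taps = taps,
            offsets = offsets)
  .convIndexCache[[key]] <- g
  g
}

# W is (kernel*Cin) x F with row block j holding tap j's Cin x F weights.
conv_fwd <- function(X, W, b, kernel, dilation, L, B,
                     activation = "relu") {
  Cin <- ncol(X)
  g <- conv_geometry(L, B, kernel, dilation)
  Xpad <- matrix(0, B * g$Lp, Cin)
  Xpad[g$center, ] <- X
  Z <- matrix(b, B * L, length(b), byrow = TRUE)
  for (j in seq_len(kernel)) {
    Wj <- W[((j - 1L) * Cin + 1L):(j * Cin), , drop = FALSE]
    Z <- Z + Xpad[g$taps[[j]], , drop = FALSE] %*% Wj
  }
  Y <- if (activation == "relu") .relu(Z) else Z
  list(Y = Y, Xpad = Xpad, g = g, Z = Z, Cin = Cin,
       activation = activation)
}

conv_bwd <- function(dY, cache, W) {
  dZ <- if (cache$activation == "relu") dY * (cache$Z > 0) else dY
  Cin <- cache$Cin
  g <- cache$g
  kernel <- length(g$taps)
  dW <- matrix(0, kernel * Cin, ncol(dZ))
  # pad dZ so that dX[t] = sum_j dZ[t - o_j] W_j' is again a tap gather
  dZpad <- matrix(0, nrow(cache$Xpad), ncol(dZ))
  dZpad[g$center, ] <- dZ
  dX <- matrix(0, nrow(dZ), Cin)
  for (j in seq_len(kernel)) {
    rows <- ((j - 1L) * Cin + 1L):(j * Cin)
    dW[rows, ] <- crossprod(cache$Xpad[g$taps[[j]], , drop = FALSE], dZ)
    dX <- dX + dZpad[g$center - g$offsets[j], , drop = FALSE] %*%
      t(W[rows, , drop = FALSE])
  }
  list(dX = dX, dW = dW, db = colSums(dZ))
}

## ---- LSTM ------------------------------------------------------------------

# Batched LSTM over L steps. p holds Wf/Wi/Wc/Wo ((H+E) x H, acting on the
# concatenation [h_{t-1}, x_t]) and bf/bi/bc/bo, following the gate
# equations: f, i and o are sigmoid gates, the candidate is tanh,
# C_t = f*C_{t-1} + i*Cand, h_t = o*tanh(C_t).
lstm_fwd <- function(X, L, B, p, reverse = FALSE) {
  H <- ncol(p$Wf)
  E <- ncol(X)
  Wcat <- cbind(p$Wf, p$Wi, p$Wc, p$Wo)
  bcat <- c(p$bf, p$bi, p$bc, p$bo)
  h <- matrix(0, B, H)
  C <- matrix(0, B, H)
  order <- if (reverse) L:1 else 1:L
  Hs <- matrix(0, B * L, H)
  steps <- vector("list", L)
  for (s in seq_len(L)) {
    t <- order[s]
    rows <- t + (0:(B - 1L)) * L
    xt <- X[rows, , drop = FALSE]
    z <- cbind(h, xt)
    G <- sweep(z %*% Wcat, 2L, bcat, "+")
    f <- .sigmoid(G[, 1:H, drop = FALSE])
    i <- .sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
    Cprev <- C
    C <- f * Cprev + i * g
    tC <- tanh(C)
    h <- o * tC
    Hs[rows, ] <- h
    steps[[s]] <- list(z = z, f = f, i = i, g = g, o = o,
                       Cprev = Cprev, tC = tC, rows = rows)
  }
  list(Y = Hs, steps = steps, H = H, E = E, L = L, B = B,
       reverse = reverse, Wcat = Wcat)
}

lstm_bwd <- function(dY, cache) {
  H <- cache$H; E <- cache$E; L <- cache$L; B <- cache$B
  Wcat <- cache$Wcat
  dWcat <- matrix(0, H + E, 4 * H)
  dbcat <- numeric(4 * H)
  dX <- matrix(0, B * L, E)
  dh_next <- matrix(0, B, H)
  dC_next <- matrix(0, B, H)
  for (s in L:1) {
    st <- cache$steps[[s]]
    dh <- dY[st$rows, , drop = FALSE] + dh_next
    do <- dh * st$tC
    dC <- dh * st$o * (1 - st$tC^2) + dC_next
    df <- dC * st$Cprev
    di <- dC * st$g
    dg <- dC * st$i
    dC_next <- dC * st$f
    dG <- cbind(df * st$f * (1 - st$f),
                di * st$i * (1 - st$i),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    dWcat <- dWcat + crossprod(st$z, dG)
    dbcat <- dbcat + colSums(dG)
    dz <- dG %*% t(Wcat)
    dh_next <- dz[, 1:H, drop = FALSE]
    dX[st$rows, ] <- dz[, (H + 1):(H + E), drop = FALSE]
  }
  list(dX = dX,
       dWf = dWcat[, 1:H, drop = FALSE],
       dWi = dWcat[, (H + 1):(2 * H), drop = FALSE],
       dWc = dWcat[, (2 * H + 1):(3 * H), drop = FALSE],
       dWo = dWcat[, (3 * H + 1):(4 * H), drop = FALSE],
       dbf = dbcat[1:H], dbi = dbcat[(H + 1):(2 * H)],
       dbc = dbcat[(2 * H + 1):(3 * H)], dbo = dbcat[(3 * H + 1):(4 * H)])
}

## ---- multi-head attention --------------------------------------------------

# Batched cross multi-head attention. Qin/Kin/Vin are (B*L) x d matrices
# (queries and keys share L here). p holds Wq/Wk/Wv/Wo (d x d, head i
# occupying column block i); h is the head count. Scaled dot-product
# similarity with 1/sqrt(d_head).
mha_fwd <- function(Qin, Kin, Vin, p, L, B, h) {
  d <- ncol(Qin)
  dh <- d %/% h
  Q <- Qin %*% p$Wq
  K <- Kin %*% p$Wk
  V <- Vin %*% p$Wv
  Concat <- matrix(0, B * L, d)
  A <- vector("list", B * h)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      S <- (Q[rows, cols, drop = FALSE] %*%
              t(K[rows, cols, drop = FALSE])) * scale
      Ab <- .softmaxRows(S)
      A[[(b - 1L) * h + i]] <- Ab
      Concat[rows, cols] <- Ab %*% V[rows, cols, drop = FALSE]
    }
  }
  Y <- Concat %*% p$Wo
  list(Y = Y, Qin = Qin, Kin = Kin, Vin = Vin, Q = Q, K = K, V = V,
       A = A, Concat = Concat, L = L, B = B, h = h, dh = dh)
}

mha_bwd <- function(dY, cache, p) {
  L <- cache$L; B <- cache$B; h <- cache$h; dh <- cache$dh
  d <- h * dh
  scale <- 1 / sqrt(dh)
  dWo <- crossprod(cache$Concat, dY)
  dConcat <- dY %*% t(p$Wo)
  dQ <- matrix(0, B * L, d)
  dK <- matrix(0, B * L, d)
  dV <- matrix(0, B * L, d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dh + 1L):(i * dh)
      Ab <- cache$A[[(b - 1L) * h + i]]
      dO <- dConcat[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- dO %*% t(Vb)
      dV[rows, cols] <- crossprod(Ab, dO)
      dS <- Ab * (dA - rowSums(dA * Ab))
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) * scale
      dK[rows, cols] <- (crossprod(dS, cache$Q[rows, cols, drop = FALSE])) *
        scale
    }
  }
  list(dQin = dQ %*% t(p$Wq), dKin = dK %*% t(p$Wk), dVin = dV %*% t(p$Wv),
       dWq = crossprod(cache$Qin, dQ), dWk = crossprod(cache$Kin, dK),
       dWv = crossprod(cache$Vin, dV), dWo = dWo)
}

## ---- reshapes --------------------------------------------------------------

# Halve length, double channels: positions (2t-1, 2t) are concatenated
# channel-wise into position t. Lossless.
downsample_fwd <- function(X, L, B) {
  if (L %% 2L != 0L) stop("downsample requires an even sequence length")
  n <- nrow(X)
  odd <- seq(1L, n, by = 2L)
  list(Y = cbind(X[odd, , drop = FALSE], X[odd + 1L, , drop = FALSE]),
       C = ncol(X))
}

downsample_bwd <- function(dY, cache) {
  C <- cache$C
  n2 <- nrow(dY)
  dX <- matrix(0, 2L * n2, C)
  odd <- seq(1L, 2L * n2, by = 2L)
  dX[odd, ] <- dY[, 1:C, drop = FALSE]
  dX[odd + 1L, ] <- dY[, (C + 1L):(2L * C), drop = FALSE]
  dX
}

# Global average pooling over positions: (B*L) x C -> B x C.
gap_fwd <- function(X, L, B) {
  grp <- rep.int(seq_len(B), rep.int(L, B))
  list(Y = rowsum(X, grp) / L, L = L, B = B)
}

gap_bwd <- function(dY, cache) {
  dY[rep.int(seq_len(cache$B), rep.int(cache$L, cache$B)), , drop = FALSE] /
    cache$L
}

## ---- embedding -------------------------------------------------------------

# tokens: B x L matrix of 0-based indices into an E-row table (pad = last).
embed_fwd <- function(tokens, E) {
  idx <- as.vector(t(tokens)) + 1L
  list(Y = E[idx, , drop = FALSE], idx = idx, nrowE = nrow(E))
}

embed_bwd <- function(dY, cache) {
  dE <- matrix(0, cache$nrowE, ncol(dY))
  agg <- rowsum(dY, cache$idx)
  dE[as.integer(rownames(agg)), ] <- agg
  dE
}

## ---- loss ------------------------------------------------------------------

# Softmax + categorical cross-entropy, mean over the batch.
softmax_ce <- function(logits, yIdx) {
  P <- .softmaxRows(logits)
  n <- nrow(P)
  picked <- P[cbind(seq_len(n), yIdx)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dLogits <- P
  dLogits[cbind(seq_len(n), yIdx)] <- dLogits[cbind(seq_len(n), yIdx)] - 1
  list(loss = loss, probs = P, dLogits = dLogits / n)
}

## ---- Adam ------------------------------------------------------------------

# params/grads are parallel nested lists of numeric arrays.
adam_init <- function(params) {
  zero <- function(p) {
    if (is.list(p)) lapply(p, zero) else array(0, dim = dim(p) %||% length(p))
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}
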