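# Independent brute-force oracles, written directly from the defining
# equations so the vectorized implementations are checked against a
# second, independent derivation.

# Scaled dot-product attention by explicit loops over queries and keys.
oracleScaledDot <- function(Q, K, V) {
  d <- ncol(Q)
  out <- matrix(0, nrow(Q), ncol(V))
  for (qi in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (ki in seq_len(nrow(K)))
      s[ki] <- sum(Q[qi, ] * K[ki, ]) / sqrt(d)
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (ki in seq_len(nrow(K)))
      out[qi, ] <- out[qi, ] + w[ki] * V[ki, ]
  }
  out
}

# Multi-head attention: run every head independently on its column
# block, concatenate in head order, apply the output projection.
oracleMultiHead <- function(Q, K, V, params) {
  d <- ncol(Q)
  h <- params$h
  dh <- d %/% h
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    heads[[i]] <- oracleScaledDot(Q %*% params$Wq[, cols, drop = FALSE],
                                  K %*% params$Wk[, cols, drop = FALSE],
                                  V %*% params$Wv[, cols, drop = FALSE])
  }
  do.call(cbind, heads) %*% params$Wo
}

# Dilated same-padded convolution by a triple loop over output
# positions, filters and taps (weights as a kernel x Cin x F array).
oracleConv1d <- function(x, weights, bias, dilation = 1L,
                         activation = "relu") {
  L <- nrow(x); Cin <- ncol(x)
  k <- dim(weights)[1]; F <- dim(weights)[3]
  left <- ((k - 1) * dilation) %/% 2
  out <- matrix(0, L, F)
  for (t in seq_len(L)) {
    for (f in seq_len(F)) {
      acc <- bias[f]
      for (j in seq_len(k)) {
        src <- t + (j - 1) * dilation - left
        if (src >= 1 && src <= L)
          acc <- acc + sum(x[src, ] * weights[j, , f])
      }
      out[t, f] <- if (activation == "relu") max(acc, 0) else acc
    }
  }
  out
}

# One LSTM step transcribed equation by equation.
oracleLstmStep <- function(x, hPrev, cPrev, p) {
  sig <- function(z) 1 / (1 + exp(-z))
  z <- c(hPrev, x)
  f <- sig(as.vector(z %*% p$Wf) + p$bf)
  i <- sig(as.vector(z %*% p$Wi) + p$bi)
  ctilde <- tanh(as.vector(z %*% p$Wc) + p$bc)
  C <- f * cPrev + i * ctilde
  o <- sig(as.vector(z %*% p$Wo) + p$bo)
  list(h = o * tanh(C), c = C)
}

# One-vs-rest confusion counts by an explicit double loop.
oracleConfusion <- function(truth, pred, families) {
  out <- matrix(0L, length(families), 4,
                dimnames = list(families, c("TP", "TN", "FP", "FN")))
  for (g in families) {
    for (i in seq_along(truth)) {
      isT <- truth[i] == g
      isP <- pred[i] == g
      if (isT && isP) out[g, "TP"] <- out[g, "TP"] + 1L
      else if (!isT && !isP) out[g, "TN"] <- out[g, "TN"] + 1L
      else if (!isT && isP) out[g, "FP"] <- out[g, "FP"] + 1L
      else out[g, "FN"] <- out[g, "FN"] + 1L
    }
  }
  out
}

# Type-7 sample quantile from first principles (sort + interpolation).
oracleQuantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Identity-projection MHA params (h = 1) for reduction tests.
identityMhaParams <- function(d) {
  list(h = 1L, Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d))
}
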