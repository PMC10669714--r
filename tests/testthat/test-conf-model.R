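# Reshape the engine's flattened (kernel*Cin) x F conv weights into the
# kernel x Cin x F array the brute-force oracle consumes.
engineWeightsToArray <- function(Wm, kernel, Cin) {
  F <- ncol(Wm)
  aperm(array(Wm, dim = c(Cin, kernel, F)), c(2, 1, 3))
}

test_that("a size-1 identity kernel passes its input channel through", {
  w <- array(0, dim = c(1, 3, 1))
  w[1, 1, 1] <- 1                      # copy channel 1
  p <- convLayerParams(1, 3, 1, activation = "linear", weights = w)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(drop(conv1d(x, p)), x[, 1], tolerance = 1e-12)
})

test_that("dilation widens the receptive field to (k-1)*d + 1 positions", {
  k <- 3; d <- 4
  w <- array(1, dim = c(k, 1, 1))
  p <- convLayerParams(k, 1, 1, dilation = d, activation = "linear",
                       weights = w)
  x <- matrix(0, 30, 1)
  x[15, 1] <- 1                        # unit impulse
  y <- drop(conv1d(x, p))
  expect_equal(sum(y != 0), k)         # k taps see the impulse
  span <- range(which(y != 0))
  expect_equal(diff(span) + 1L, (k - 1L) * d + 1L)
})

test_that("conv1d matches the triple-loop oracle, with and without dilation", {
  set.seed(21)
  x <- matrix(rnorm(30), 10, 3)
  for (d in c(1L, 2L)) {
    p <- convLayerParams(3, 3, 2, dilation = d, seed = 22)
    expect_equal(conv1d(x, p),
                 oracleConv1d(x, p$weights, p$bias, d, "relu"),
                 tolerance = 1e-12)
  }
  expect_error(conv1d(matrix(0, 5, 2), convLayerParams(3, 3, 2, seed = 1)),
               "channels")
})

test_that("an all-zero LSTM step follows the closed form", {
  H <- 3
  p <- lstmParams(2, H, seed = 23, forgetBias = 0)
  for (nm in c("Wf", "Wi", "Wc", "Wo")) p[[nm]][] <- 0
  cPrev <- c(1, -2, 0.5)
  st <- lstmStep(c(0.3, -0.1), numeric(H), cPrev, p)
  # f = i = o = sigmoid(0) = 0.5, candidate = tanh(0) = 0
  expect_equal(st$c, 0.5 * cPrev, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(0.5 * cPrev), tolerance = 1e-12)
  st0 <- lstmStep(c(0.3, -0.1), numeric(H), numeric(H), p)
  expect_equal(st0$h, numeric(H), tolerance = 1e-15)
})

test_that("the LSTM step matches the six-equation oracle to 1e-10", {
  set.seed(24)
  p <- lstmParams(4, 3, seed = 25)
  x <- rnorm(4); h <- rnorm(3); cc <- rnorm(3)
  st <- lstmStep(x, h, cc, p)
  or <- oracleLstmStep(x, h, cc, p)
  expect_equal(st$h, or$h, tolerance = 1e-10)
  expect_equal(st$c, or$c, tolerance = 1e-10)
  expect_error(lstmStep(rnorm(4), rnorm(2), rnorm(3), p), "hidden size")
})

test_that("BiLSTM encodes each position at twice the hidden width", {
  set.seed(26)
  fwd <- lstmParams(16, 16, seed = 27)
  bwd <- lstmParams(16, 16, seed = 28)
  x <- matrix(rnorm(5 * 16), 5, 16)
  y <- bilstmEncode(x, fwd, bwd)
  expect_equal(dim(y), c(5L, 32L))
})

test_that("reversing the input and swapping directions mirrors the encoding", {
  set.seed(29)
  fwd <- lstmParams(3, 2, seed = 30)
  bwd <- lstmParams(3, 2, seed = 31)
  x <- matrix(rnorm(12), 4, 3)
  y <- bilstmEncode(x, fwd, bwd)
  y2 <- bilstmEncode(x[4:1, , drop = FALSE], bwd, fwd)
  expect_equal(y2, y[4:1, c(3:4, 1:2)], tolerance = 1e-12)
})

test_that("BiLSTM equals two independent unidirectional oracle runs", {
  set.seed(32)
  H <- 2; E <- 3; L <- 3
  fwd <- lstmParams(E, H, seed = 33)
  bwd <- lstmParams(E, H, seed = 34)
  x <- matrix(rnorm(L * E), L, E)
  run <- function(p, order) {
    h <- numeric(H); cc <- numeric(H)
    out <- matrix(0, L, H)
    for (t in order) {
      st <- oracleLstmStep(x[t, ], h, cc, p)
      h <- st$h; cc <- st$c
      out[t, ] <- h
    }
    out
  }
  expect_equal(bilstmEncode(x, fwd, bwd),
               cbind(run(fwd, 1:L), run(bwd, L:1)), tolerance = 1e-12)
})

test_that("the front end concatenates BiLSTM then CNN channels", {
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 35)
  v <- kmerVocabulary(cfg$k)
  tok <- tokenizeSequence(randomRna(20), v, cfg$maxLen)
  fr <- frontend(tok, cfg, params)
  d <- 2 * cfg$lstmHidden + cfg$cnnFilters
  expect_equal(dim(fr), c(cfg$maxLen, d))
  # BiLSTM slice
  emb <- params$embedding[tok + 1L, ]
  lstmF <- params$lstmFwd; class(lstmF) <- "LSTMParams"
  lstmB <- params$lstmBwd; class(lstmB) <- "LSTMParams"
  expect_equal(fr[, 1:(2 * cfg$lstmHidden)],
               bilstmEncode(emb, lstmF, lstmB), tolerance = 1e-12)
  # CNN slice: two stacked same-padded ReLU convolutions
  w1 <- engineWeightsToArray(params$cnn[[1]]$W, cfg$cnnKernels[1],
                             cfg$embeddingDim)
  w2 <- engineWeightsToArray(params$cnn[[2]]$W, cfg$cnnKernels[2],
                             cfg$cnnFilters)
  c1 <- oracleConv1d(emb, w1, params$cnn[[1]]$b)
  c2 <- oracleConv1d(c1, w2, params$cnn[[2]]$b)
  expect_equal(fr[, (2 * cfg$lstmHidden + 1):d], c2, tolerance = 1e-10)
})

test_that("an all-pad token window still yields finite features", {
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 36)
  pad <- rep(kmerVocabulary(cfg$k)@padIndex, cfg$maxLen)
  expect_true(all(is.finite(frontend(pad, cfg, params))))
  expect_true(all(is.finite(confForward(pad, cfg, params))))
})

test_that("MLP-attention fusion preserves shape and reduces to identity", {
  set.seed(37)
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 38)
  x <- matrix(rnorm(16 * 8), 16, 8)
  y <- mlpAttentionFuse(x, params$fuse, nHeads = cfg$nHeads)
  expect_equal(dim(y), dim(x))
  pz <- params$fuse
  pz$mha$Wo[] <- 0
  expect_identical(mlpAttentionFuse(x, pz, nHeads = cfg$nHeads), x)
  # equals the composition of the verified pieces
  deep <- sweep(pmax(sweep(x %*% pz$W1, 2, pz$b1, "+"), 0) %*% pz$W2,
                2, pz$b2, "+")
  mh <- c(list(h = cfg$nHeads), params$fuse$mha)
  expect_equal(y, crossResidualFuse(x, deep, mh), tolerance = 1e-10)
})

test_that("the residual block preserves shape and degenerates to identity", {
  set.seed(39)
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 40)
  d <- 2 * cfg$lstmHidden + cfg$cnnFilters
  x <- matrix(rnorm(8 * d), 8, d)
  y <- convBlock(x, params$block1, kernels = cfg$blockKernels,
                 dilations = cfg$blockDilations, nHeads = cfg$nHeads)
  expect_equal(dim(y), dim(x))
  pz <- params$block1
  pz$mha$Wo[] <- 0
  expect_identical(convBlock(x, pz, kernels = cfg$blockKernels,
                             dilations = cfg$blockDilations,
                             nHeads = cfg$nHeads), x)
  expect_error(convBlock(x[, 1:3], params$block1), "channels")
})

test_that("the residual block equals the composition of verified pieces", {
  set.seed(41)
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 42)
  d <- 2 * cfg$lstmHidden + cfg$cnnFilters
  x <- matrix(rnorm(8 * d), 8, d)
  p <- params$block1
  branches <- lapply(1:3, function(i)
    oracleConv1d(x, engineWeightsToArray(p$convs[[i]]$W,
                                         cfg$blockKernels[i], d),
                 p$convs[[i]]$b, cfg$blockDilations[i]))
  deep <- sweep(do.call(cbind, branches) %*% p$projW, 2, p$projb, "+")
  mh <- c(list(h = cfg$nHeads), p$mha)
  expect_equal(convBlock(x, p, kernels = cfg$blockKernels,
                         dilations = cfg$blockDilations,
                         nHeads = cfg$nHeads),
               crossResidualFuse(x, deep, mh), tolerance = 1e-10)
})

test_that("downsampling reshapes losslessly with the index arithmetic", {
  x <- matrix(as.numeric(seq_len(8 * 4)), 8, 4)   # numbered grid
  y <- downsample(x)
  expect_equal(dim(y), c(4L, 8L))
  # 0-based: out[t, c] = in[2t + floor(c/C), c mod C]
  C <- 4
  for (t0 in 0:3) for (c0 in 0:7)
    expect_equal(y[t0 + 1, c0 + 1],
                 x[2 * t0 + c0 %/% C + 1, c0 %% C + 1])
  expect_identical(upsample(y), x)
  expect_error(downsample(matrix(0, 7, 4)), "even")
})

test_that("forward yields a probability simplex and uniform output for a zero head", {
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 43)
  tok <- tokenizeSequence(randomRna(25), kmerVocabulary(cfg$k), cfg$maxLen)
  p1 <- confForward(tok, cfg, params)
  expect_length(p1, cfg$nClasses)
  expect_true(all(p1 >= 0))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  # deterministic in inference
  expect_identical(p1, confForward(tok, cfg, params))
  # zeroed final fully connected layer -> softmax of zeros -> uniform
  params$head$W2[] <- 0
  params$head$b2[] <- 0
  expect_equal(unname(confForward(tok, cfg, params)),
               rep(1 / cfg$nClasses, cfg$nClasses), tolerance = 1e-12)
})

test_that("stage shapes follow the documented pipeline on the full config", {
  cfg <- modelConfig()                  # 224-window, 128-channel default
  params <- initModelParams(cfg, seed = 44)
  tok <- tokenizeSequence(randomRna(150), kmerVocabulary(2), 224)
  out <- rnafamnet:::conf_batch(matrix(tok, nrow = 1), cfg, params)
  st <- out$stages
  expect_equal(dim(st$frontend), c(224L, 128L))
  expect_equal(dim(st$fused), c(224L, 128L))
  expect_equal(dim(st$block1), c(224L, 128L))
  expect_equal(dim(st$down), c(112L, 256L))
  expect_equal(dim(st$block2), c(112L, 256L))
  expect_length(drop(out$probs), 13L)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 45)
  v <- kmerVocabulary(cfg$k)
  set.seed(46)
  tok <- rbind(tokenizeSequence(randomRna(20), v, cfg$maxLen),
               tokenizeSequence(randomRna(30), v, cfg$maxLen))
  y <- c(1L, 3L)
  out <- rnafamnet:::conf_batch(tok, cfg, params, y)
  getL <- function(p, path) { for (k in path) p <- p[[k]]; p }
  setL <- function(p, path, val) {
    if (length(path) == 1L) { p[[path[[1]]]] <- val; return(p) }
    p[[path[[1]]]] <- setL(p[[path[[1]]]], path[-1], val)
    p
  }
  paths <- list(list("embedding"), list("lstmFwd", "Wc"),
                list("lstmBwd", "bf"), list("cnn", 1L, "W"),
                list("fuse", "W1"), list("fuse", "mha", "Wq"),
                list("block1", "convs", 2L, "W"), list("block1", "projW"),
                list("block2", "mha", "Wo"), list("head", "W2"))
  eps <- 1e-5
  for (path in paths) {
    leaf <- getL(params, path)
    g <- getL(out$grads, path)
    i <- which.max(abs(g))             # strongest-gradient entry
    l2 <- leaf; l2[i] <- leaf[i] + eps
    lp <- rnafamnet:::conf_batch(tok, cfg, setL(params, path, l2), y)$loss
    l2[i] <- leaf[i] - eps
    lm <- rnafamnet:::conf_batch(tok, cfg, setL(params, path, l2), y)$loss
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-8), 1e-4)
  }
})
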