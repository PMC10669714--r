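#' Network configuration
#'
#' Hyperparameters of the classifier. The defaults are the full-size
#' network: a 224-token 2-mer window embedded at dimension 16, a BiLSTM
#' with 16 hidden units per direction alongside a dual-layer CNN with 96
#' filters (kernel 5), so the concatenated front end is 224 x 128; an
#' MLP-plus-attention fusion; Block 1 with three parallel convolution
#' branches (window 16, and dilated windows 10 and 18 at dilation 2);
#' a lossless downsampling to 112 x 256; Block 2 with the same structure
#' and twice the filters; global average pooling and a fully connected
#' softmax head over 13 families.
#'
#' @param k K-mer length for tokenization (default 2).
#' @param maxLen Token window length (default 224; must be even for the
#'   downsampling stage).
#' @param embeddingDim Embedding dimension (default 16).
#' @param lstmHidden Hidden units per LSTM direction (default 16, so the
#'   BiLSTM encodes each position as a 1 x 32 vector).
#' @param cnnFilters Filters in each CNN front-end layer (default 96, so
#'   BiLSTM + CNN channels concatenate to 128).
#' @param cnnKernels Kernel sizes of the two stacked front-end
#'   convolution layers.
#' @param blockKernels Window sizes of the three parallel block branches.
#' @param blockDilations Dilation of each block branch.
#' @param blockFilters Filters per branch in Block 1 (Block 2 uses twice
#'   as many).
#' @param nHeads Attention heads in every cross-attention fusion.
#' @param nClasses Number of families (default 13).
#' @param mlpHidden Hidden width of the position-wise MLP in the fusion
#'   stage and of the classifier head.
#' @return A list of class \code{"ConfModelConfig"}.
#' @examples
#' cfg <- modelConfig()
#' cfg$maxLen
#' @export
modelConfig <- function(k = 2L, maxLen = 224L, embeddingDim = 16L,
                        lstmHidden = 16L, cnnFilters = 96L,
                        cnnKernels = c(5L, 5L),
                        blockKernels = c(16L, 10L, 18L),
                        blockDilations = c(1L, 2L, 2L),
                        blockFilters = 128L, nHeads = 4L, nClasses = 13L,
                        mlpHidden = 128L) {
  cfg <- list(k = as.integer(k), maxLen = as.integer(maxLen),
              embeddingDim = as.integer(embeddingDim),
              lstmHidden = as.integer(lstmHidden),
              cnnFilters = as.integer(cnnFilters),
              cnnKernels = as.integer(cnnKernels),
              blockKernels = as.integer(blockKernels),
              blockDilations = as.integer(blockDilations),
              blockFilters = as.integer(blockFilters),
              nHeads = as.integer(nHeads), nClasses = as.integer(nClasses),
              mlpHidden = as.integer(mlpHidden))
  if (cfg$maxLen %% 2L != 0L)
    stop("maxLen must be even (the downsampling stage halves it)")
  if (length(cfg$cnnKernels) != 2L)
    stop("cnnKernels must give the two stacked front-end kernel sizes")
  if (length(cfg$blockKernels) != 3L ||
      length(cfg$blockDilations) != 3L)
    stop("blockKernels/blockDilations must describe three branches")
  d <- 2L * cfg$lstmHidden + cfg$cnnFilters
  if (d %% cfg$nHeads != 0L)
    stop(sprintf("nHeads = %d must divide the model width %d",
                 cfg$nHeads, d))
  class(cfg) <- "ConfModelConfig"
  cfg
}

# Model width after the front end: BiLSTM (2H) + CNN filters.
dModelOf <- function(cfg) 2L * cfg$lstmHidden + cfg$cnnFilters

#' @export
print.ConfModelConfig <- function(x, ...) {
  d <- dModelOf(x)
  cat(sprintf(
    "Model config: %d-mer window %d, embed %d, BiLSTM %d/dir + CNN %d -> %d channels,\n",
    x$k, x$maxLen, x$embeddingDim, x$lstmHidden, x$cnnFilters, d))
  cat(sprintf(
    "  blocks: kernels %s (dilations %s), %d/%d filters, %d heads, %d classes\n",
    paste(x$blockKernels, collapse = "/"),
    paste(x$blockDilations, collapse = "/"),
    x$blockFilters, 2L * x$blockFilters, x$nHeads, x$nClasses))
  invisible(x)
}

## ---- parameter constructors -----------------------------------------------

#' Convolution layer parameters
#'
#' A same-padded, optionally dilated 1-D convolution layer: output
#' position \code{t}, filter \code{j} is the activation of
#' \code{sum_{taps, in-channels} x[t + offset, c] * w[tap, c, j] + b[j]},
#' where the taps are spaced \code{dilation} positions apart (receptive
#' field \code{(kernel-1)*dilation + 1}) and positions outside the input
#' contribute zero.
#'
#' @param kernel Kernel size (number of taps).
#' @param inChannels Input channels (fan-in per tap).
#' @param filters Number of output filters.
#' @param dilation Tap spacing (>= 1).
#' @param activation \code{"relu"} or \code{"linear"}.
#' @param weights Optional \code{kernel x inChannels x filters} array;
#'   Glorot-initialized when omitted.
#' @param bias Optional length-\code{filters} vector (zeros when omitted).
#' @param seed Optional seed for initialization.
#' @return A list of class \code{"ConvLayerParams"}.
#' @export
convLayerParams <- function(kernel, inChannels, filters, dilation = 1L,
                            activation = c("relu", "linear"),
                            weights = NULL, bias = NULL, seed = NULL) {
  activation <- match.arg(activation)
  kernel <- as.integer(kernel)
  if (kernel < 1L || dilation < 1L)
    stop("kernel and dilation must be >= 1")
  if (is.null(weights)) {
    init <- function() array(
      runif(kernel * inChannels * filters,
            -sqrt(6 / (kernel * inChannels + filters)),
            sqrt(6 / (kernel * inChannels + filters))),
      dim = c(kernel, inChannels, filters))
    weights <- if (is.null(seed)) init() else withSeed(seed, init())
  }
  if (!identical(dim(weights), c(kernel, as.integer(inChannels),
                                 as.integer(filters))))
    stop("weights must be a kernel x inChannels x filters array")
  if (is.null(bias)) bias <- numeric(filters)
  structure(list(kernel = kernel, inChannels = as.integer(inChannels),
                 filters = as.integer(filters),
                 dilation = as.integer(dilation), activation = activation,
                 weights = weights, bias = bias),
            class = "ConvLayerParams")
}

# Flatten a kernel x Cin x F weight array to the (kernel*Cin) x F matrix
# the engine multiplies im2col columns with (tap j = row block j).
.convWeightMatrix <- function(weights) {
  d <- dim(weights)
  matrix(aperm(weights, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

#' Apply a 1-D convolution layer to a feature map
#'
#' @param x Feature map, \code{L x inChannels} matrix.
#' @param params A \code{\link{convLayerParams}} object.
#' @return \code{L x filters} matrix.
#' @examples
#' p <- convLayerParams(3, 2, 2, seed = 1)
#' dim(conv1d(matrix(rnorm(20), 10, 2), p))
#' @export
conv1d <- function(x, params) {
  x <- as.matrix(x)
  if (ncol(x) != params$inChannels)
    stop(sprintf("input has %d channels but the layer expects %d",
                 ncol(x), params$inChannels))
  conv_fwd(x, .convWeightMatrix(params$weights), params$bias,
           params$kernel, params$dilation, nrow(x), 1L,
           params$activation)$Y
}

#' LSTM parameters
#'
#' The four gate weight matrices and biases of an LSTM cell. Each matrix
#' maps the concatenation \code{[h_prev, x]} (length \code{hidden +
#' inputDim}) to \code{hidden} outputs: \code{Wf/bf} the forget gate,
#' \code{Wi/bi} the input gate, \code{Wc/bc} the candidate cell state,
#' \code{Wo/bo} the output gate.
#'
#' @param inputDim Input width per step.
#' @param hidden Hidden state size.
#' @param seed Optional seed for Glorot initialization.
#' @param forgetBias Initial forget-gate bias (1 by default, a standard
#'   aid to gradient flow early in training).
#' @return A list of class \code{"LSTMParams"}.
#' @export
lstmParams <- function(inputDim, hidden, seed = NULL, forgetBias = 1) {
  make <- function() list(
    Wf = .glorot(hidden + inputDim, hidden),
    Wi = .glorot(hidden + inputDim, hidden),
    Wc = .glorot(hidden + inputDim, hidden),
    Wo = .glorot(hidden + inputDim, hidden),
    bf = rep(forgetBias, hidden), bi = numeric(hidden),
    bc = numeric(hidden), bo = numeric(hidden))
  p <- if (is.null(seed)) make() else withSeed(seed, make())
  class(p) <- "LSTMParams"
  p
}

#' One LSTM step
#'
#' The gate equations of a single time step: forget gate
#' \code{f = sigmoid(Wf [h_prev, x] + bf)}, input gate
#' \code{i = sigmoid(Wi [h_prev, x] + bi)}, candidate
#' \code{c~ = tanh(Wc [h_prev, x] + bc)}, cell state
#' \code{C = f * C_prev + i * c~}, output gate
#' \code{o = sigmoid(Wo [h_prev, x] + bo)}, hidden state
#' \code{h = o * tanh(C)}.
#'
#' @param x Input vector for this step.
#' @param hPrev,cPrev Previous hidden and cell state vectors.
#' @param params An \code{\link{lstmParams}} object.
#' @return List with elements \code{h} and \code{c}.
#' @export
lstmStep <- function(x, hPrev, cPrev, params) {
  H <- ncol(params$Wf)
  if (length(hPrev) != H || length(cPrev) != H)
    stop("hPrev and cPrev must have length equal to the hidden size")
  z <- c(hPrev, x)
  if (length(z) != nrow(params$Wf))
    stop("input dimension does not match the gate weight matrices")
  f <- .sigmoid(drop(z %*% params$Wf) + params$bf)
  i <- .sigmoid(drop(z %*% params$Wi) + params$bi)
  g <- tanh(drop(z %*% params$Wc) + params$bc)
  o <- .sigmoid(drop(z %*% params$Wo) + params$bo)
  C <- f * cPrev + i * g
  list(h = o * tanh(C), c = C)
}

#' BiLSTM encoding of a feature map
#'
#' Runs a forward LSTM left to right and a backward LSTM right to left
#' over the rows of \code{x} (both starting from zero states) and
#' concatenates the per-position hidden states \code{[h_fwd; h_bwd]}, so
#' each position is encoded as a vector of width \code{2 * hidden}
#' (1 x 32 under the default 16-unit directions).
#'
#' @param x Feature map, \code{L x inputDim}.
#' @param fwd,bwd \code{\link{lstmParams}} for the two directions.
#' @return \code{L x (2 * hidden)} matrix.
#' @export
bilstmEncode <- function(x, fwd, bwd) {
  x <- as.matrix(x)
  L <- nrow(x)
  cbind(lstm_fwd(x, L, 1L, fwd, reverse = FALSE)$Y,
        lstm_fwd(x, L, 1L, bwd, reverse = TRUE)$Y)
}

## ---- full parameter set ----------------------------------------------------

.mhaMatrices <- function(d) list(
  Wq = .glorot(d, d), Wk = .glorot(d, d),
  Wv = .glorot(d, d), Wo = .glorot(d, d))

.convMatrix <- function(kernel, cin, f) {
  lim <- sqrt(6 / (kernel * cin + f))
  list(W = matrix(runif(kernel * cin * f, -lim, lim), kernel * cin, f),
       b = numeric(f))
}

.blockParams <- function(cfg, d, filters) {
  list(convs = list(.convMatrix(cfg$blockKernels[1L], d, filters),
                    .convMatrix(cfg$blockKernels[2L], d, filters),
                    .convMatrix(cfg$blockKernels[3L], d, filters)),
       projW = .glorot(3L * filters, d), projb = numeric(d),
       mha = .mhaMatrices(d))
}

#' Initialize the full parameter set of the network
#'
#' Glorot-uniform weights throughout, zero biases (forget-gate bias 1),
#' a learned embedding table with \code{4^k + 1} rows (the extra row is
#' the padding token).
#'
#' @param cfg A \code{\link{modelConfig}}.
#' @param seed Optional seed; when \code{NULL} the current RNG state is
#'   used (as during seeded training).
#' @return Nested list of parameter arrays (embedding, lstmFwd, lstmBwd,
#'   cnn, fuse, block1, block2, head).
#' @export
initModelParams <- function(cfg, seed = NULL) {
  make <- function() {
    d <- dModelOf(cfg)
    E <- cfg$embeddingDim
    H <- cfg$lstmHidden
    lstmInit <- function() list(
      Wf = .glorot(H + E, H), Wi = .glorot(H + E, H),
      Wc = .glorot(H + E, H), Wo = .glorot(H + E, H),
      bf = rep(1, H), bi = numeric(H), bc = numeric(H), bo = numeric(H))
    list(
      embedding = .glorot(4L^cfg$k + 1L, E),
      lstmFwd = lstmInit(),
      lstmBwd = lstmInit(),
      cnn = list(.convMatrix(cfg$cnnKernels[1L], E, cfg$cnnFilters),
                 .convMatrix(cfg$cnnKernels[2L], cfg$cnnFilters,
                             cfg$cnnFilters)),
      fuse = list(W1 = .glorot(d, cfg$mlpHidden), b1 = numeric(cfg$mlpHidden),
                  W2 = .glorot(cfg$mlpHidden, d), b2 = numeric(d),
                  mha = .mhaMatrices(d)),
      block1 = .blockParams(cfg, d, cfg$blockFilters),
      block2 = .blockParams(cfg, 2L * d, 2L * cfg$blockFilters),
      head = list(W1 = .glorot(2L * d, cfg$mlpHidden),
                  b1 = numeric(cfg$mlpHidden),
                  W2 = .glorot(cfg$mlpHidden, cfg$nClasses),
                  b2 = numeric(cfg$nClasses)))
  }
  if (is.null(seed)) make() else withSeed(seed, make())
}

## ---- internal staged forward/backward -------------------------------------

# Front end: embedding -> {BiLSTM || dual-layer CNN} -> channel concat.
frontend_fwd <- function(tokens, cfg, params) {
  B <- nrow(tokens); L <- ncol(tokens)
  emb <- embed_fwd(tokens, params$embedding)
  lf <- lstm_fwd(emb$Y, L, B, params$lstmFwd, reverse = FALSE)
  lb <- lstm_fwd(emb$Y, L, B, params$lstmBwd, reverse = TRUE)
  c1 <- conv_fwd(emb$Y, params$cnn[[1L]]$W, params$cnn[[1L]]$b,
                 cfg$cnnKernels[1L], 1L, L, B, "relu")
  c2 <- conv_fwd(c1$Y, params$cnn[[2L]]$W, params$cnn[[2L]]$b,
                 cfg$cnnKernels[2L], 1L, L, B, "relu")
  list(Y = cbind(lf$Y, lb$Y, c2$Y),
       emb = emb, lf = lf, lb = lb, c1 = c1, c2 = c2, L = L, B = B)
}

frontend_bwd <- function(dY, cache, cfg, params) {
  H <- cfg$lstmHidden
  dlf <- dY[, 1:H, drop = FALSE]
  dlb <- dY[, (H + 1L):(2L * H), drop = FALSE]
  dc2 <- dY[, (2L * H + 1L):ncol(dY), drop = FALSE]
  rf <- lstm_bwd(dlf, cache$lf)
  rb <- lstm_bwd(dlb, cache$lb)
  cb2 <- conv_bwd(dc2, cache$c2, params$cnn[[2L]]$W)
  cb1 <- conv_bwd(cb2$dX, cache$c1, params$cnn[[1L]]$W)
  dX0 <- rf$dX + rb$dX + cb1$dX
  lstmGrad <- function(r) list(Wf = r$dWf, Wi = r$dWi, Wc = r$dWc,
                               Wo = r$dWo, bf = r$dbf, bi = r$dbi,
                               bc = r$dbc, bo = r$dbo)
  list(grads = list(
         embedding = embed_bwd(dX0, cache$emb),
         lstmFwd = lstmGrad(rf), lstmBwd = lstmGrad(rb),
         cnn = list(list(W = cb1$dW, b = cb1$db),
                    list(W = cb2$dW, b = cb2$db))))
}

# MLP + cross-attention fusion: deep = MLP(x); y = x + MHA(x, deep, deep).
fuse_fwd <- function(X, cfg, p, L, B) {
  m1 <- dense_fwd(X, p$W1, p$b1)
  m1r <- .relu(m1$Y)
  m2 <- dense_fwd(m1r, p$W2, p$b2)
  att <- mha_fwd(X, m2$Y, m2$Y, p$mha, L, B, cfg$nHeads)
  list(Y = X + att$Y, m1 = m1, m2 = m2, att = att)
}

fuse_bwd <- function(dY, cache, p) {
  datt <- mha_bwd(dY, cache$att, p$mha)
  dDeep <- datt$dKin + datt$dVin
  d2 <- dense_bwd(dDeep, cache$m2, p$W2)
  dm1 <- d2$dX * (cache$m1$Y > 0)
  d1 <- dense_bwd(dm1, cache$m1, p$W1)
  list(dX = dY + datt$dQin + d1$dX,
       grads = list(W1 = d1$dW, b1 = d1$db, W2 = d2$dW, b2 = d2$db,
                    mha = list(Wq = datt$dWq, Wk = datt$dWk,
                               Wv = datt$dWv, Wo = datt$dWo)))
}

# Residual block: three parallel conv branches -> concat -> width-1
# projection (the deep path), fused back onto x by cross attention.
block_fwd <- function(X, cfg, p, L, B) {
  br <- vector("list", 3L)
  for (i in 1:3)
    br[[i]] <- conv_fwd(X, p$convs[[i]]$W, p$convs[[i]]$b,
                        cfg$blockKernels[i], cfg$blockDilations[i],
                        L, B, "relu")
  cat3 <- cbind(br[[1L]]$Y, br[[2L]]$Y, br[[3L]]$Y)
  proj <- dense_fwd(cat3, p$projW, p$projb)
  att <- mha_fwd(X, proj$Y, proj$Y, p$mha, L, B, cfg$nHeads)
  list(Y = X + att$Y, br = br, proj = proj, att = att)
}

block_bwd <- function(dY, cache, cfg, p) {
  datt <- mha_bwd(dY, cache$att, p$mha)
  dDeep <- datt$dKin + datt$dVin
  dproj <- dense_bwd(dDeep, cache$proj, p$projW)
  dX <- dY + datt$dQin
  f <- vapply(cache$br, function(b) ncol(b$Y), integer(1))
  off <- c(0L, cumsum(f))
  convGrads <- vector("list", 3L)
  for (i in 1:3) {
    cb <- conv_bwd(dproj$dX[, (off[i] + 1L):off[i + 1L], drop = FALSE],
                   cache$br[[i]], p$convs[[i]]$W)
    dX <- dX + cb$dX
    convGrads[[i]] <- list(W = cb$dW, b = cb$db)
  }
  list(dX = dX,
       grads = list(convs = convGrads, projW = dproj$dW, projb = dproj$db,
                    mha = list(Wq = datt$dWq, Wk = datt$dWk,
                               Wv = datt$dWv, Wo = datt$dWo)))
}

# Full batched pass. tokens: B x L matrix of 0-based indices. With yIdx
# (1-based class indices) also computes loss and all parameter gradients.
conf_batch <- function(tokens, cfg, params, yIdx = NULL) {
  B <- nrow(tokens); L <- ncol(tokens)
  fr <- frontend_fwd(tokens, cfg, params)
  fu <- fuse_fwd(fr$Y, cfg, params$fuse, L, B)
  b1 <- block_fwd(fu$Y, cfg, params$block1, L, B)
  ds <- downsample_fwd(b1$Y, L, B)
  L2 <- L %/% 2L
  b2 <- block_fwd(ds$Y, cfg, params$block2, L2, B)
  g <- gap_fwd(b2$Y, L2, B)
  h1 <- dense_fwd(g$Y, params$head$W1, params$head$b1)
  h1r <- .relu(h1$Y)
  lg <- dense_fwd(h1r, params$head$W2, params$head$b2)
  probs <- .softmaxRows(lg$Y)
  if (is.null(yIdx))
    return(list(probs = probs, stages = list(
      frontend = fr$Y, fused = fu$Y, block1 = b1$Y, down = ds$Y,
      block2 = b2$Y)))
  sm <- softmax_ce(lg$Y, yIdx)
  dlg <- dense_bwd(sm$dLogits, lg, params$head$W2)
  dh1 <- dlg$dX * (h1$Y > 0)
  dd1 <- dense_bwd(dh1, h1, params$head$W1)
  dx8 <- gap_bwd(dd1$dX, g)
  r2 <- block_bwd(dx8, b2, cfg, params$block2)
  dx6 <- downsample_bwd(r2$dX, ds)
  r1 <- block_bwd(dx6, b1, cfg, params$block1)
  rf <- fuse_bwd(r1$dX, fu, params$fuse)
  rfr <- frontend_bwd(rf$dX, fr, cfg, params)
  grads <- c(rfr$grads,
             list(fuse = rf$grads, block1 = r1$grads, block2 = r2$grads,
                  head = list(W1 = dd1$dW, b1 = dd1$db,
                              W2 = dlg$dW, b2 = dlg$db)))
  list(loss = sm$loss, probs = sm$probs, grads = grads)
}

# Chunked inference over many token rows; returns the probability matrix.
predict_tokens <- function(tokens, cfg, params, chunk = 256L) {
  n <- nrow(tokens)
  out <- matrix(0, n, cfg$nClasses)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- conf_batch(tokens[s:e, , drop = FALSE], cfg, params)$probs
  }
  out
}

## ---- exported single-sequence stages --------------------------------------

#' Front-end features for one token sequence
#'
#' Embedding lookup followed by the parallel BiLSTM and dual-layer CNN
#' branches, channel-concatenated (BiLSTM forward states, BiLSTM backward
#' states, then CNN filters) — 224 x 128 under the default configuration.
#'
#' @param tokens Integer vector from \code{\link{tokenizeSequence}} (or a
#'   1-row matrix of 0-based indices).
#' @param cfg A \code{\link{modelConfig}}.
#' @param params Parameters from \code{\link{initModelParams}}.
#' @return \code{maxLen x dModel} feature matrix.
#' @export
frontend <- function(tokens, cfg, params) {
  tok <- matrix(as.integer(tokens), nrow = 1L)
  frontend_fwd(tok, cfg, params)$Y
}

#' MLP + attention fusion of a feature map
#'
#' Maps \code{x} through a two-layer position-wise MLP (ReLU after the
#' first layer) and fuses the result back onto \code{x} with
#' cross multi-head attention: \code{x + MHA(Q = x, K = V = MLP(x))}.
#' Shape is preserved.
#'
#' @param x \code{L x dModel} feature matrix.
#' @param params The \code{fuse} component of
#'   \code{\link{initModelParams}} output (elements \code{W1, b1, W2, b2,
#'   mha}).
#' @param nHeads Attention heads.
#' @return Matrix of the same shape as \code{x}.
#' @export
mlpAttentionFuse <- function(x, params, nHeads = 4L) {
  x <- as.matrix(x)
  cfg <- list(nHeads = as.integer(nHeads))
  fuse_fwd(x, cfg, params, nrow(x), 1L)$Y
}

#' Multi-scale residual block with attention-based residual
#'
#' Three parallel convolution branches (one plain window and two dilated
#' windows) are concatenated and projected back to the input width by a
#' width-1 convolution — the deep path \code{F(x)} — then fused onto the
#' input by cross multi-head attention: \code{x + MHA(x, F(x), F(x))}.
#' With a zero attention output projection the block degenerates to the
#' identity mapping, the classical residual behaviour when
#' \code{F(x) = 0}.
#'
#' @param x \code{L x C} feature matrix; \code{C} must match the block's
#'   parameters.
#' @param params A block component (\code{block1} or \code{block2}) of
#'   \code{\link{initModelParams}} output.
#' @param kernels,dilations Window sizes and dilations of the three
#'   branches.
#' @param nHeads Attention heads.
#' @return Matrix of the same shape as \code{x}.
#' @export
convBlock <- function(x, params, kernels = c(16L, 10L, 18L),
                      dilations = c(1L, 2L, 2L), nHeads = 4L) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(params$mha$Wq))
    stop(sprintf("feature map has %d channels but block expects %d",
                 ncol(x), nrow(params$mha$Wq)))
  cfg <- list(blockKernels = as.integer(kernels),
              blockDilations = as.integer(dilations),
              nHeads = as.integer(nHeads))
  block_fwd(x, cfg, params, nrow(x), 1L)$Y
}

#' Lossless downsampling by positional reshaping
#'
#' Concatenates each pair of adjacent positions channel-wise: the
#' sequence length is halved and the channel (embedding) dimension
#' doubled, with no information lost — (224, 128) becomes (112, 256).
#'
#' @param x \code{L x C} matrix with even \code{L}.
#' @return \code{(L/2) x 2C} matrix.
#' @export
downsample <- function(x) {
  x <- as.matrix(x)
  downsample_fwd(x, nrow(x), 1L)$Y
}

#' Inverse of \code{\link{downsample}}
#'
#' @param y \code{(L/2) x 2C} matrix.
#' @return The original \code{L x C} matrix.
#' @export
upsample <- function(y) {
  y <- as.matrix(y)
  C <- ncol(y) %/% 2L
  x <- matrix(0, 2L * nrow(y), C)
  odd <- seq(1L, nrow(x), by = 2L)
  x[odd, ] <- y[, 1:C, drop = FALSE]
  x[odd + 1L, ] <- y[, (C + 1L):(2L * C), drop = FALSE]
  x
}

#' Full forward pass for one sequence
#'
#' Front end, MLP-attention fusion, Block 1, downsampling, Block 2,
#' global average pooling and the fully connected softmax head. The
#' returned class probabilities are non-negative and sum to one.
#'
#' @inheritParams frontend
#' @return Named numeric vector of \code{nClasses} probabilities (names
#'   are class indices unless \code{classNames} is given).
#' @param classNames Optional class labels for the output names.
#' @export
confForward <- function(tokens, cfg, params, classNames = NULL) {
  tok <- matrix(as.integer(tokens), nrow = 1L)
  p <- drop(conf_batch(tok, cfg, params)$probs)
  names(p) <- if (is.null(classNames)) as.character(seq_along(p)) else
    classNames
  p
}
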