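#' Multi-head attention parameters
#'
#' Bundles the per-head query/key/value projections and the output
#' projection of a multi-head attention layer. Head \code{i} of \code{h}
#' occupies column block \code{i} of the \code{dModel x dModel} matrices
#' \code{Wq}, \code{Wk}, \code{Wv} (each block is that head's
#' \code{dModel x dHead} projection, with \code{dHead = dModel / h} so
#' concatenating the heads restores the model width); \code{Wo} is the
#' \code{(h * dHead) x dModel} output projection applied after
#' concatenation.
#'
#' @param dModel Model width (number of channels of the attended features).
#' @param nHeads Number of heads \code{h}; must divide \code{dModel}.
#' @param seed Optional seed for the Glorot-uniform initialization; when
#'   \code{NULL} the current RNG state is used.
#' @return A list with elements \code{h}, \code{Wq}, \code{Wk}, \code{Wv},
#'   \code{Wo}.
#' @examples
#' p <- mhaParams(8, nHeads = 2, seed = 1)
#' dim(p$Wq)
#' @export
mhaParams <- function(dModel, nHeads = 4L, seed = NULL) {
  dModel <- as.integer(dModel)
  nHeads <- as.integer(nHeads)
  if (dModel %% nHeads != 0L)
    stop(sprintf("nHeads = %d must divide dModel = %d", nHeads, dModel))
  make <- function() list(
    h = nHeads,
    Wq = .glorot(dModel, dModel), Wk = .glorot(dModel, dModel),
    Wv = .glorot(dModel, dModel), Wo = .glorot(dModel, dModel))
  if (is.null(seed)) make() else withSeed(seed, make())
}

#' Scaled dot-product attention
#'
#' Computes \code{softmax(Q K' / sqrt(d)) V}, where \code{d} is the key
#' width: the similarity between every query and key row is the scaled
#' dot product, each row of similarities is normalized to a probability
#' simplex by the softmax, and the output is the weight-averaged value
#' rows. Every attention-weight row therefore sums to one.
#'
#' @param Q Query matrix (\code{nq x d}).
#' @param K Key matrix (\code{nk x d}).
#' @param V Value matrix (\code{nk x dv}).
#' @param returnWeights If \code{TRUE}, attach the \code{nq x nk} weight
#'   matrix as attribute \code{"weights"}.
#' @return \code{nq x dv} matrix.
#' @examples
#' Q <- diag(2); K <- diag(2); V <- matrix(1:4, 2)
#' scaledDotAttention(Q, K, V)
#' @export
scaledDotAttention <- function(Q, K, V, returnWeights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    stop("Q and K must have the same number of columns")
  if (nrow(K) != nrow(V))
    stop("K and V must have the same number of rows")
  A <- .softmaxRows(Q %*% t(K) / sqrt(ncol(Q)))
  out <- A %*% V
  if (returnWeights) attr(out, "weights") <- A
  out
}

#' Cross multi-head attention
#'
#' Projects queries, keys and values into \code{h} subspaces (column
#' blocks of the projection matrices), runs scaled dot-product attention
#' independently per head, concatenates the head outputs in head order
#' and applies the output projection. Queries may come from a different
#' feature set than keys/values (cross attention); the output has one row
#' per query row and \code{dModel} columns.
#'
#' @param Q,K,V Matrices of width \code{dModel} (\code{K} and \code{V}
#'   with equal row counts).
#' @param params Parameters from \code{\link{mhaParams}}.
#' @return \code{nrow(Q) x dModel} matrix.
#' @export
multiHeadAttention <- function(Q, K, V, params) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d <- ncol(Q)
  h <- params$h
  if (ncol(K) != d || ncol(V) != d)
    stop("Q, K and V must all have width dModel")
  if (nrow(params$Wq) != d)
    stop(sprintf("params are for dModel = %d, inputs have width %d",
                 nrow(params$Wq), d))
  if (d %% h != 0L)
    stop(sprintf("head count %d incompatible with dModel = %d", h, d))
  dh <- d %/% h
  Qp <- Q %*% params$Wq
  Kp <- K %*% params$Wk
  Vp <- V %*% params$Wv
  Concat <- matrix(0, nrow(Q), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    Concat[, cols] <- scaledDotAttention(
      Qp[, cols, drop = FALSE], Kp[, cols, drop = FALSE],
      Vp[, cols, drop = FALSE])
  }
  Concat %*% params$Wo
}

#' Attention-mediated residual fusion of shallow and deep features
#'
#' The residual combiner of the network: instead of adding the deep
#' branch element-wise to the shallow branch, cross multi-head attention
#' compares them — queries come from the shallow features, keys and
#' values from the deep features — and the attention output is added to
#' the shallow features. With a zero output projection this reduces
#' exactly to the identity on \code{shallow}, mirroring the classical
#' residual identity mapping when the learned mapping is zero.
#'
#' @param shallow,deep Feature matrices of identical shape
#'   (\code{L x dModel}).
#' @param params Parameters from \code{\link{mhaParams}}.
#' @return Matrix of the same shape as \code{shallow}.
#' @export
crossResidualFuse <- function(shallow, deep, params) {
  shallow <- as.matrix(shallow); deep <- as.matrix(deep)
  if (!identical(dim(shallow), dim(deep)))
    stop("shallow and deep feature maps must have identical shapes")
  shallow + multiHeadAttention(shallow, deep, deep, params)
}
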