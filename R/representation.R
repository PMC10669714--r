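#' K-mer vocabulary for RNA tokenization
#'
#' Enumerates all \code{4^k} k-mers over the RNA alphabet in lexicographic
#' A < C < G < U order and assigns them 0-based integer indices
#' (\code{AA -> 0}, ..., \code{UU -> 15} for k = 2). The index \code{4^k}
#' is reserved for the padding token; the embedding table therefore has
#' \code{4^k + 1} rows and the pad embedding is learned like any other.
#'
#' @slot k K-mer length.
#' @slot tokens Character vector of the \code{4^k} k-mers in index order.
#' @slot padIndex The reserved padding index, \code{4^k}.
#' @export
setClass("KmerVocabulary",
  slots = c(k = "integer", tokens = "character", padIndex = "integer"))

setValidity("KmerVocabulary", function(object) {
  if (length(object@tokens) != 4L^object@k)
    return("tokens must enumerate all 4^k k-mers")
  if (object@padIndex != 4L^object@k)
    return("padIndex must equal 4^k")
  TRUE
})

setMethod("show", "KmerVocabulary", function(object) {
  cat(sprintf("KmerVocabulary: k = %d, %d tokens + pad (index %d)\n",
              object@k, length(object@tokens), object@padIndex))
})

#' Build the k-mer vocabulary
#'
#' @param k K-mer length, between 1 and 4.
#' @return A \code{\linkS4class{KmerVocabulary}}.
#' @examples
#' v <- kmerVocabulary(2)
#' head(v@tokens)   # "AA" "AC" "AG" "AU" "CA" "CC"
#' @export
kmerVocabulary <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 4L)
    stop("k must be an integer between 1 and 4")
  bases <- c("A", "C", "G", "U")
  tokens <- bases
  if (k > 1L) for (i in 2:k)
    tokens <- as.vector(t(outer(tokens, bases, paste0)))
  new("KmerVocabulary", k = k, tokens = tokens,
      padIndex = as.integer(4^k))
}

#' @rdname kmerVocabulary
#' @param vocab A \code{KmerVocabulary}.
#' @return \code{vocabSize}: number of embedding rows, \code{4^k + 1}
#'   (k-mers plus the pad token).
#' @export
vocabSize <- function(vocab) length(vocab@tokens) + 1L

# 0-based base codes A=0 C=1 G=2 U=3, as an integer lookup over raw chars.
.baseCode <- local({
  m <- rep(NA_integer_, 128L)
  m[utf8ToInt("A")] <- 0L; m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L; m[utf8ToInt("U")] <- 3L
  m
})

#' Tokenize one RNA sequence into a fixed-length k-mer index vector
#'
#' Overlapping k-mers (stride 1) are mapped to their 0-based vocabulary
#' indices; the result is right-padded with the pad index to
#' \code{maxLen}, or truncated at \code{maxLen} keeping the 5' prefix.
#' The number of real (non-pad) tokens is
#' \code{min(nchar(seq) - k + 1, maxLen)} and is attached as the
#' \code{"nReal"} attribute.
#'
#' @param seq A single RNA sequence (character, already ACGU-normalized;
#'   \code{\link{RNAFamilySet}} ingestion guarantees this).
#' @param vocab A \code{\linkS4class{KmerVocabulary}}.
#' @param maxLen Token window length; default 224.
#' @return Integer vector of length \code{maxLen} with attribute
#'   \code{nReal}.
#' @examples
#' v <- kmerVocabulary(2)
#' t <- tokenizeSequence("ACGU", v, maxLen = 8)
#' t[1:3]                  # indices of AC, CG, GU
#' attr(t, "nReal")        # 3
#' @export
tokenizeSequence <- function(seq, vocab, maxLen = 224L) {
  stopifnot(is(vocab, "KmerVocabulary"), length(seq) == 1L)
  k <- vocab@k
  n <- nchar(seq)
  if (n < k)
    stop(sprintf("sequence of length %d is shorter than k = %d", n, k))
  codes <- .baseCode[utf8ToInt(as.character(seq))]
  if (anyNA(codes))
    stop("sequence contains non-ACGU characters; normalize it first")
  m <- n - k + 1L
  val <- integer(m)
  for (j in seq_len(k)) val <- val * 4L + codes[j:(m + j - 1L)]
  nReal <- min(m, as.integer(maxLen))
  out <- c(val[seq_len(nReal)],
           rep(vocab@padIndex, as.integer(maxLen) - nReal))
  structure(out, nReal = nReal)
}

#' Tokenize every record of a dataset
#'
#' @param x An \code{\linkS4class{RNAFamilySet}}.
#' @inheritParams tokenizeSequence
#' @return Integer matrix (records x \code{maxLen}) of 0-based token
#'   indices, rownames = ids, with attribute \code{nReal} (integer vector).
#' @export
tokenizeSet <- function(x, vocab, maxLen = 224L) {
  stopifnot(is(x, "RNAFamilySet"))
  seqs <- as.character(sequences(x))
  toks <- lapply(seqs, tokenizeSequence, vocab = vocab, maxLen = maxLen)
  out <- do.call(rbind, toks)
  rownames(out) <- seqIds(x)
  structure(out, nReal = vapply(toks, attr, integer(1), "nReal"))
}

#' Reconstruct the sequence prefix from non-pad tokens
#'
#' Overlapping stride-1 k-mers are invertible on the covered prefix: the
#' first token contributes k residues and each later token one more.
#' Useful for round-trip checks.
#'
#' @param indices Integer vector of 0-based token indices (pad allowed as
#'   a suffix).
#' @param vocab The \code{\linkS4class{KmerVocabulary}} used to tokenize.
#' @return Single character string, the reconstructed prefix.
#' @export
detokenize <- function(indices, vocab) {
  real <- indices[indices != vocab@padIndex]
  if (!length(real)) return("")
  toks <- vocab@tokens[real + 1L]
  paste0(toks[1L], paste(substring(toks[-1L], vocab@k, vocab@k),
                         collapse = ""))
}
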