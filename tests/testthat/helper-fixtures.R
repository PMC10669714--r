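# Shared small fixtures built in code.

# A miniature model configuration for fast engine-level tests.
tinyModelConfig <- function(nClasses = 3L) {
  modelConfig(k = 2L, maxLen = 16L, embeddingDim = 4L, lstmHidden = 2L,
              cnnFilters = 4L, blockFilters = 4L, nHeads = 2L,
              nClasses = nClasses, mlpHidden = 6L)
}

# The scaled-down demonstration configuration used for the held-out
# training checks: 64-token 2-mer window, model width 32.
scaledModelConfig <- function(nClasses = 4L) {
  modelConfig(k = 2L, maxLen = 64L, embeddingDim = 8L, lstmHidden = 8L,
              cnnFilters = 16L, blockFilters = 16L, nHeads = 4L,
              nClasses = nClasses, mlpHidden = 32L)
}

randomRna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Random token matrix (0-based indices incl. pad) for a given config.
randomTokens <- function(nSeq, cfg) {
  v <- kmerVocabulary(cfg$k)
  do.call(rbind, lapply(seq_len(nSeq), function(i)
    tokenizeSequence(randomRna(sample(20:60, 1)), v, cfg$maxLen)))
}

# A small labeled set with two clearly separable families.
twoFamilySet <- function(perFamily = 20L, seed = 11L) {
  generateEasyFamilySet(nFamilies = 2L, perFamily = perFamily,
                        mutationRate = 0, seed = seed,
                        lengthLaw = c(30, 40, 50))
}
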