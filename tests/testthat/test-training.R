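test_that("training history has one row per epoch and is seed-reproducible", {
  ds <- twoFamilySet(perFamily = 10L)
  plan <- makeFolds(ds, 2, seed = 71)
  cfg <- tinyModelConfig(nClasses = 2L)
  tc <- trainConfig(epochs = 3, batchSize = 8, seed = 72)
  r1 <- suppressWarnings(trainFold(ds, plan, 1, cfg, tc))
  expect_equal(nrow(r1$history), 3L)
  expect_true(all(is.finite(r1$history$trainLoss)))
  expect_true(all(r1$history$trainAcc >= 0 & r1$history$trainAcc <= 1))
  r2 <- suppressWarnings(trainFold(ds, plan, 1, cfg, tc))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("training loss descends on separable data", {
  ds <- twoFamilySet(perFamily = 15L)
  plan <- makeFolds(ds, 3, seed = 73)
  cfg <- tinyModelConfig(nClasses = 2L)
  tc <- trainConfig(epochs = 5, batchSize = 10, seed = 74)
  r <- suppressWarnings(trainFold(ds, plan, 1, cfg, tc))
  expect_lt(r$history$trainLoss[5], r$history$trainLoss[1])
})

test_that("a fold whose training partition lacks a family is rejected", {
  ds <- twoFamilySet(perFamily = 6L)
  a <- setNames(rep(2L, length(ds)), seqIds(ds))
  a[as.character(familyOf(ds)) == "fam1"] <- 1L   # all of fam1 in fold 1
  plan <- new("FoldPlan", nFolds = 2L, assignments = a, seed = 0L)
  expect_error(trainFold(ds, plan, 1, tinyModelConfig(2L),
                         trainConfig(epochs = 1, batchSize = 4)),
               "fam1")
  expect_error(trainFold(ds, plan, 5, tinyModelConfig(2L),
                         trainConfig(epochs = 1, batchSize = 4)),
               "foldIndex")
})

test_that("a class-count mismatch between model and data is an error", {
  ds <- twoFamilySet(perFamily = 6L)
  plan <- makeFolds(ds, 2, seed = 75)
  expect_error(trainFold(ds, plan, 1, tinyModelConfig(nClasses = 3L),
                         trainConfig(epochs = 1, batchSize = 4)),
               "classes")
})

test_that("cross-validation tests every record exactly once and averages folds", {
  ds <- generateEasyFamilySet(nFamilies = 3, perFamily = 20, seed = 76,
                              lengthLaw = c(30, 40, 50))
  cv <- crossValidate(ds, tinyModelConfig(3L),
                      trainConfig(epochs = 1, batchSize = 8, seed = 77),
                      nFolds = 5, engine = kmerCentroidEngine())
  expect_setequal(cv$predictions$id, seqIds(ds))
  expect_equal(nrow(cv$predictions), length(ds))
  accs <- vapply(cv$folds, function(f) f$metrics@accuracy, numeric(1))
  expect_equal(cv$aggregate[["accuracy"]], mean(accs), tolerance = 1e-12)
  expect_equal(dim(cv$perFoldF1), c(5L, 3L))
})

test_that("a two-fold end-to-end run with the network engine completes", {
  ds <- twoFamilySet(perFamily = 8L)
  cv <- crossValidate(ds, tinyModelConfig(2L),
                      trainConfig(epochs = 2, batchSize = 8, seed = 78),
                      nFolds = 2)
  expect_length(cv$folds, 2L)
  expect_equal(nrow(cv$folds[[1]]$history), 2L)
  expect_true(all(cv$aggregate >= 0 & cv$aggregate <= 1))
})

test_that("the k-mer sweep reports one distribution per k with 4^k vocabularies", {
  ds <- generateEasyFamilySet(nFamilies = 3, perFamily = 12, seed = 79,
                              lengthLaw = c(30, 40, 50))
  sw <- kmerSweep(ds, ks = c(1, 2, 3), tinyModelConfig(3L),
                  trainConfig(epochs = 1, batchSize = 8, seed = 80),
                  nFolds = 4, engine = kmerCentroidEngine())
  expect_length(sw, 3L)
  expect_equal(vapply(sw, `[[`, integer(1), "vocabSize"),
               c(k1 = 4L, k2 = 16L, k3 = 64L))
  for (e in sw) {
    expect_length(e$accuracies, 4L)
    # five-number summary against a first-principles quantile oracle
    expect_equal(e$summary,
                 vapply(c(0, 0.25, 0.5, 0.75, 1), function(p)
                   oracleQuantile(e$accuracies, p), numeric(1)),
                 tolerance = 1e-12)
  }
  expect_error(kmerSweep(ds, ks = 5), "1..4")
})

test_that("the robustness protocol yields disjoint subsets with full coverage", {
  ds <- generateEasyFamilySet(nFamilies = 2, perFamily = 60, seed = 81,
                              lengthLaw = c(30, 40, 50))
  rb <- robustnessProtocol(ds, tinyModelConfig(2L),
                           trainConfig(epochs = 1, batchSize = 8,
                                       seed = 82),
                           nSubsets = 3, nFolds = 4,
                           engine = majorityClassEngine())
  expect_length(rb, 3L)
  ids <- lapply(rb, `[[`, "ids")
  expect_equal(sum(lengths(ids)), length(ds))
  expect_equal(length(unique(unlist(ids))), length(ds))   # disjoint
  for (e in rb) expect_length(e$accuracies, 4L)
  expect_error(
    robustnessProtocol(ds, tinyModelConfig(2L),
                       trainConfig(epochs = 1, batchSize = 8),
                       nSubsets = 3, nFolds = 30),
    "too small")
})

test_that("a majority-class stub scores exactly the majority fraction per fold", {
  # unbalanced families so the majority fraction is informative
  big <- generateFamily(familySpec("maj", 30, lengthLaw = c(30, 35, 40)),
                        seed = 83)
  small <- generateFamily(familySpec("min", 10, lengthLaw = c(30, 35, 40)),
                          seed = 84)
  ds <- combineFamilySets(list(big, small))
  cv <- crossValidate(ds, tinyModelConfig(2L),
                      trainConfig(epochs = 1, batchSize = 8, seed = 85),
                      nFolds = 5, engine = majorityClassEngine())
  a <- foldAssignments(cv$plan)[seqIds(ds)]
  for (fi in 1:5) {
    foldFams <- as.character(familyOf(ds))[a == fi]
    expect_equal(cv$foldAccuracies[fi], mean(foldFams == "maj"),
                 tolerance = 1e-12)
  }
})

test_that("training remains finite with the attention residuals disabled", {
  cfg <- tinyModelConfig(2L)
  params <- initModelParams(cfg, seed = 86)
  params$fuse$mha$Wo[] <- 0
  params$block1$mha$Wo[] <- 0
  params$block2$mha$Wo[] <- 0
  set.seed(87)
  tok <- randomTokens(8, cfg)
  y <- rep(1:2, 4)
  state <- rnafamnet:::adam_init(params)
  for (step in 1:5) {
    out <- rnafamnet:::conf_batch(tok, cfg, params, y)
    expect_true(is.finite(out$loss))
    st <- rnafamnet:::adam_step(params, out$grads, state, 0.001)
    params <- st$params
    state <- st$state
  }
  expect_true(all(is.finite(rnafamnet:::predict_tokens(tok, cfg, params))))
})
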