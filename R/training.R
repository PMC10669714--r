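#' Training configuration
#'
#' Hyperparameters of a training run. Defaults are the full-scale
#' settings: learning rate 0.001, 220 epochs, batch size 200,
#' categorical cross-entropy loss, Adam optimizer (default moments).
#' Scaled-down experiments pass smaller \code{epochs}/\code{batchSize}.
#'
#' @param learningRate Positive step size (default 0.001).
#' @param epochs Number of passes over the training data (default 220).
#' @param batchSize Mini-batch size (default 200).
#' @param optimizer Only \code{"adam"} is implemented.
#' @param loss Only \code{"categorical_crossentropy"} is implemented.
#' @param seed Integer seed controlling parameter initialization and
#'   batch shuffling (and fold plans in the protocols).
#' @return A list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(learningRate = 0.001, epochs = 220L,
                        batchSize = 200L, optimizer = "adam",
                        loss = "categorical_crossentropy", seed = 1L) {
  if (learningRate <= 0) stop("learningRate must be > 0")
  epochs <- as.integer(epochs); batchSize <- as.integer(batchSize)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batchSize < 1L) stop("batchSize must be >= 1")
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "categorical_crossentropy")
  structure(list(learningRate = learningRate, epochs = epochs,
                 batchSize = batchSize, optimizer = optimizer,
                 loss = loss, seed = as.integer(seed)),
            class = "TrainConfig")
}

# Core seeded training loop on pre-tokenized arrays. trY/vaY are factors
# over the same levels; the number of levels must match cfg$nClasses.
# Returns params, per-epoch history and validation predictions.
train_on_arrays <- function(trTok, trY, vaTok, vaY, cfg, tcfg, seed) {
  nClasses <- nlevels(trY)
  if (nClasses != cfg$nClasses)
    stop(sprintf("model is configured for %d classes but data has %d",
                 cfg$nClasses, nClasses))
  yIdx <- as.integer(trY)
  n <- nrow(trTok)
  history <- data.frame(epoch = seq_len(tcfg$epochs), trainLoss = NA_real_,
                        trainAcc = NA_real_, valAcc = NA_real_)
  res <- withSeed(seed, {
    params <- initModelParams(cfg)
    state <- adam_init(params)
    for (ep in seq_len(tcfg$epochs)) {
      perm <- sample.int(n)
      lossSum <- 0; correct <- 0L
      for (s in seq(1L, n, by = tcfg$batchSize)) {
        idx <- perm[s:min(s + tcfg$batchSize - 1L, n)]
        out <- conf_batch(trTok[idx, , drop = FALSE], cfg, params,
                          yIdx[idx])
        lossSum <- lossSum + out$loss * length(idx)
        correct <- correct + sum(max.col(out$probs,
                                         ties.method = "first") ==
                                   yIdx[idx])
        st <- adam_step(params, out$grads, state, tcfg$learningRate)
        params <- st$params
        state <- st$state
      }
      history$trainLoss[ep] <- lossSum / n
      history$trainAcc[ep] <- correct / n
      if (!is.null(vaTok) && nrow(vaTok) > 0L) {
        vp <- predict_tokens(vaTok, cfg, params)
        history$valAcc[ep] <- mean(max.col(vp, ties.method = "first") ==
                                     as.integer(vaY))
      }
    }
    list(params = params)
  })
  valProbs <- if (!is.null(vaTok) && nrow(vaTok) > 0L)
    predict_tokens(vaTok, cfg, res$params) else NULL
  valPred <- if (!is.null(valProbs))
    factor(levels(trY)[max.col(valProbs, ties.method = "first")],
           levels = levels(trY)) else NULL
  list(params = res$params, history = history, valPred = valPred,
       valProbs = valProbs)
}

# Engine interface: function(trainSet, testSet, modelCfg, trainCfg, seed)
# -> list(pred = factor over the test set, history = data.frame or NULL).

#' Training engines for the evaluation protocols
#'
#' \code{confEngine} trains the full network (the default everywhere).
#' \code{majorityClassEngine} predicts the most frequent training family
#' for every test record, and \code{kmerCentroidEngine} applies
#' \code{\link{kmerCentroidBaseline}}; both are cheap stand-ins used to
#' exercise and test the cross-validation protocols themselves.
#'
#' @return A function with signature \code{(trainSet, testSet, modelCfg,
#'   trainCfg, seed)} returning \code{list(pred, history)}.
#' @export
confEngine <- function() {
  function(trainSet, testSet, modelCfg, trainCfg, seed) {
    vocab <- kmerVocabulary(modelCfg$k)
    trTok <- tokenizeSet(trainSet, vocab, modelCfg$maxLen)
    teTok <- tokenizeSet(testSet, vocab, modelCfg$maxLen)
    fit <- train_on_arrays(trTok, familyOf(trainSet), teTok,
                           familyOf(testSet), modelCfg, trainCfg, seed)
    list(pred = fit$valPred, history = fit$history, params = fit$params)
  }
}

#' @rdname confEngine
#' @export
majorityClassEngine <- function() {
  function(trainSet, testSet, modelCfg, trainCfg, seed) {
    tab <- table(familyOf(trainSet))
    top <- names(tab)[which.max(tab)]
    list(pred = factor(rep(top, length(testSet)),
                       levels = familyLevels(trainSet)),
         history = NULL)
  }
}

#' @rdname confEngine
#' @param k K-mer length for the centroid baseline.
#' @export
kmerCentroidEngine <- function(k = 2L) {
  function(trainSet, testSet, modelCfg, trainCfg, seed) {
    list(pred = kmerCentroidBaseline(trainSet, testSet, k = k),
         history = NULL)
  }
}

# Seed for fold `i` of a run seeded with `seed`, kept below 2^31.
foldSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% .Machine$integer.max)
}

#' Train on all folds but one, evaluate on the held-out fold
#'
#' Trains the network on every fold except \code{foldIndex} and
#' evaluates on \code{foldIndex}. Fully reproducible given the fold plan
#' and \code{trainCfg$seed}: parameter initialization and batch
#' shuffling derive from a per-fold seed.
#'
#' @param dataset An \code{\linkS4class{RNAFamilySet}}.
#' @param foldPlan A \code{\linkS4class{FoldPlan}} for the dataset.
#' @param foldIndex Which fold (1-based) to hold out.
#' @param modelCfg A \code{\link{modelConfig}}.
#' @param trainCfg A \code{\link{trainConfig}}.
#' @return A list of class \code{"FoldResult"}: \code{foldIndex},
#'   \code{history} (per-epoch trainLoss, trainAcc, valAcc),
#'   \code{metrics} (macro \code{\linkS4class{MetricsReport}}),
#'   \code{perFamily} (per-class metric table), \code{predictions}
#'   (id, truth, pred) and the trained \code{params}.
#' @export
trainFold <- function(dataset, foldPlan, foldIndex, modelCfg = modelConfig(),
                      trainCfg = trainConfig()) {
  stopifnot(is(dataset, "RNAFamilySet"), is(foldPlan, "FoldPlan"))
  foldIndex <- as.integer(foldIndex)
  if (foldIndex < 1L || foldIndex > foldPlan@nFolds)
    stop("foldIndex must lie in 1..nFolds")
  assign <- foldAssignments(foldPlan)[seqIds(dataset)]
  testIds <- names(assign)[assign == foldIndex]
  trainIds <- names(assign)[assign != foldIndex]
  if (!length(trainIds)) stop("training partition is empty")
  trainSet <- dataset[trainIds]
  testSet <- dataset[testIds]
  missing <- setdiff(familyLevels(dataset),
                     unique(as.character(familyOf(trainSet))))
  if (length(missing))
    stop("family '", missing[1L], "' has no training members in this fold")
  eng <- confEngine()
  fit <- eng(trainSet, testSet, modelCfg, trainCfg,
             foldSeed(trainCfg$seed, foldIndex))
  cc <- confusionCounts(familyOf(testSet), fit$pred,
                        familyLevels(dataset))
  metrics <- classificationMetrics(cc, "macro")
  structure(list(foldIndex = foldIndex, history = fit$history,
                 metrics = metrics, perFamily = metrics@perClass,
                 predictions = data.frame(
                   id = testIds,
                   truth = as.character(familyOf(testSet)),
                   pred = as.character(fit$pred),
                   stringsAsFactors = FALSE),
                 params = fit$params),
            class = "FoldResult")
}

#' @export
print.FoldResult <- function(x, ...) {
  cat(sprintf("FoldResult (fold %d): %d test records\n", x$foldIndex,
              nrow(x$predictions)))
  show(x$metrics)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Builds a stratified fold plan seeded with \code{trainCfg$seed}, runs
#' the engine on every fold (training on the rest), and aggregates: the
#' reported metrics are the arithmetic mean of the per-fold macro
#' metrics, and every record is tested exactly once.
#'
#' @inheritParams trainFold
#' @param nFolds Number of folds (default 10).
#' @param engine Optional engine (see \code{\link{confEngine}});
#'   defaults to training the full network.
#' @param foldPlan Optional pre-built plan (otherwise derived from
#'   \code{trainCfg$seed}).
#' @return A list of class \code{"CrossValidation"}: \code{folds}
#'   (per-fold results), \code{aggregate} (mean accuracy, sensitivity,
#'   precision, f1), \code{foldAccuracies}, \code{perFoldF1} (folds x
#'   families matrix), \code{predictions} (pooled), \code{plan}.
#' @export
crossValidate <- function(dataset, modelCfg = modelConfig(),
                          trainCfg = trainConfig(), nFolds = 10L,
                          engine = NULL, foldPlan = NULL) {
  stopifnot(is(dataset, "RNAFamilySet"))
  if (is.null(engine)) engine <- confEngine()
  if (is.null(foldPlan)) foldPlan <- makeFolds(dataset, nFolds,
                                               trainCfg$seed)
  nFolds <- foldPlan@nFolds
  fams <- familyLevels(dataset)
  assign <- foldAssignments(foldPlan)[seqIds(dataset)]
  folds <- vector("list", nFolds)
  perFoldF1 <- matrix(NA_real_, nFolds, length(fams),
                      dimnames = list(NULL, fams))
  preds <- vector("list", nFolds)
  for (fi in seq_len(nFolds)) {
    testIds <- names(assign)[assign == fi]
    trainIds <- names(assign)[assign != fi]
    fit <- engine(dataset[trainIds], dataset[testIds], modelCfg, trainCfg,
                  foldSeed(trainCfg$seed, fi))
    cc <- confusionCounts(familyOf(dataset[testIds]), fit$pred, fams)
    met <- suppressWarnings(classificationMetrics(cc, "macro"))
    perFoldF1[fi, ] <- met@perClass$f1
    folds[[fi]] <- list(foldIndex = fi, metrics = met,
                        history = fit$history)
    preds[[fi]] <- data.frame(id = testIds,
                              truth = as.character(familyOf(dataset[testIds])),
                              pred = as.character(fit$pred),
                              fold = fi, stringsAsFactors = FALSE)
  }
  agg <- c(accuracy = mean(vapply(folds, function(f) f$metrics@accuracy,
                                  numeric(1))),
           sensitivity = mean(vapply(folds, function(f)
             f$metrics@sensitivity, numeric(1))),
           precision = mean(vapply(folds, function(f)
             f$metrics@precision, numeric(1))),
           f1 = mean(vapply(folds, function(f) f$metrics@f1, numeric(1))))
  overall <- vapply(folds, function(f) f$metrics@overallAccuracy,
                    numeric(1))
  structure(list(folds = folds, aggregate = agg,
                 foldAccuracies = overall, perFoldF1 = perFoldF1,
                 predictions = do.call(rbind, preds), plan = foldPlan),
            class = "CrossValidation")
}

#' @export
print.CrossValidation <- function(x, ...) {
  cat(sprintf("CrossValidation: %d folds, %d records\n",
              length(x$folds), nrow(x$predictions)))
  cat(sprintf(
    "  mean macro metrics: accuracy %.4f, sensitivity %.4f, precision %.4f, F1 %.4f\n",
    x$aggregate[["accuracy"]], x$aggregate[["sensitivity"]],
    x$aggregate[["precision"]], x$aggregate[["f1"]]))
  cat(sprintf("  per-fold overall accuracy: %s\n",
              paste(sprintf("%.3f", x$foldAccuracies), collapse = " ")))
  invisible(x)
}

#' Cross-validated comparison of k-mer lengths
#'
#' Runs the same cross-validation (same fold plan and per-fold seeds)
#' once per k-mer length and collects the per-fold accuracy
#' distribution for each, with five-number summaries for box plots.
#'
#' @inheritParams crossValidate
#' @param ks Integer vector of k-mer lengths (1 to 4).
#' @return A list of class \code{"KmerSweep"}, one element per k with
#'   \code{k}, \code{vocabSize} (\code{4^k}), \code{accuracies} and
#'   \code{summary} (min, q1, median, q3, max).
#' @export
kmerSweep <- function(dataset, ks = c(1L, 2L, 3L),
                      modelCfg = modelConfig(), trainCfg = trainConfig(),
                      nFolds = 10L, engine = NULL) {
  ks <- as.integer(ks)
  if (any(ks < 1L | ks > 4L)) stop("k values must lie in 1..4")
  plan <- makeFolds(dataset, nFolds, trainCfg$seed)
  out <- lapply(ks, function(k) {
    cfg <- modelCfg
    cfg$k <- k
    eng <- if (is.null(engine)) confEngine() else engine
    cv <- crossValidate(dataset, cfg, trainCfg, engine = eng,
                        foldPlan = plan)
    acc <- cv$foldAccuracies
    list(k = k, vocabSize = as.integer(4^k), accuracies = acc,
         summary = stats::quantile(acc, c(0, 0.25, 0.5, 0.75, 1),
                                   names = FALSE))
  })
  names(out) <- paste0("k", ks)
  class(out) <- "KmerSweep"
  out
}

#' @export
print.KmerSweep <- function(x, ...) {
  for (e in x)
    cat(sprintf("k = %d (vocab %d): median acc %.4f [%.4f, %.4f]\n",
                e$k, e$vocabSize, e$summary[3L], e$summary[1L],
                e$summary[5L]))
  invisible(x)
}

#' Five-subset robustness protocol
#'
#' Partitions the dataset into \code{nSubsets} disjoint stratified
#' subsets and runs an independent, distinctly seeded k-fold
#' cross-validation inside each, yielding one accuracy distribution per
#' subset — the box-plot robustness protocol.
#'
#' @inheritParams crossValidate
#' @param nSubsets Number of disjoint subsets (default 5).
#' @return A list of class \code{"RobustnessResult"} with one element
#'   per subset: \code{subset}, \code{ids}, \code{accuracies},
#'   \code{aggregate}.
#' @export
robustnessProtocol <- function(dataset, modelCfg = modelConfig(),
                               trainCfg = trainConfig(), nSubsets = 5L,
                               nFolds = 10L, engine = NULL) {
  subsetPlan <- makeFolds(dataset, nSubsets, trainCfg$seed)
  seeds <- childSeeds(trainCfg$seed, nSubsets)
  assign <- foldAssignments(subsetPlan)[seqIds(dataset)]
  out <- lapply(seq_len(nSubsets), function(s) {
    ids <- names(assign)[assign == s]
    sub <- dataset[ids]
    counts <- table(familyOf(sub))
    if (any(counts < nFolds))
      stop(sprintf(
        "subset %d is too small for %d folds (family '%s' has %d members)",
        s, nFolds, names(counts)[which.min(counts)], min(counts)))
    tc <- trainCfg
    tc$seed <- seeds[s]
    cv <- crossValidate(sub, modelCfg, tc, nFolds = nFolds,
                        engine = engine)
    list(subset = s, ids = ids, accuracies = cv$foldAccuracies,
         aggregate = cv$aggregate)
  })
  class(out) <- "RobustnessResult"
  out
}

#' Predict families for new sequences
#'
#' @param dataset An \code{\linkS4class{RNAFamilySet}} (labels ignored)
#'   or a character vector of sequences.
#' @param params Trained parameters (e.g. from
#'   \code{\link{trainFold}}'s \code{params} element).
#' @param modelCfg The \code{\link{modelConfig}} used in training.
#' @param classNames Family labels in training order.
#' @return A list with \code{pred} (factor) and \code{probs} (matrix).
#' @export
predictFamilies <- function(dataset, params, modelCfg, classNames) {
  if (is.character(dataset))
    dataset <- RNAFamilySet(dataset,
                            rep(classNames[1L], length(dataset)),
                            ids = paste0("q", seq_along(dataset)))
  vocab <- kmerVocabulary(modelCfg$k)
  tok <- tokenizeSet(dataset, vocab, modelCfg$maxLen)
  probs <- predict_tokens(tok, modelCfg, params)
  colnames(probs) <- classNames
  rownames(probs) <- seqIds(dataset)
  list(pred = factor(classNames[max.col(probs, ties.method = "first")],
                     levels = classNames),
       probs = probs)
}
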