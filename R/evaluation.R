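#' Per-class confusion counts
#'
#' One-vs-rest confusion counts for a multiclass prediction: for every
#' class, TP (predicted and true), TN (neither), FP (predicted, not
#' true), FN (true, not predicted). Each class's four counts sum to the
#' total number of predictions, and the TP column sums to the number of
#' correct predictions.
#'
#' @slot counts Integer matrix, classes x c(TP, TN, FP, FN).
#' @slot n Total number of predictions.
#' @export
setClass("ConfusionCounts",
  slots = c(counts = "matrix", n = "integer"))

setValidity("ConfusionCounts", function(object) {
  cc <- object@counts
  if (!identical(colnames(cc), c("TP", "TN", "FP", "FN")))
    return("counts columns must be TP, TN, FP, FN")
  if (any(cc < 0)) return("counts must be non-negative")
  if (any(rowSums(cc) != object@n))
    return("each class's counts must sum to the total prediction count")
  TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts over %d predictions, %d classes\n",
              object@n, nrow(object@counts)))
  print(object@counts)
})

#' Compute confusion counts from labels
#'
#' @param truth,pred Label vectors of equal length (character or factor).
#' @param families Class vocabulary; defaults to the union of levels of
#'   \code{truth}. Labels outside it are an error.
#' @return A \code{\linkS4class{ConfusionCounts}}.
#' @examples
#' cc <- confusionCounts(c("a", "b", "a"), c("a", "b", "b"), c("a", "b"))
#' cc@counts
#' @export
confusionCounts <- function(truth, pred, families = NULL) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  if (is.null(families))
    families <- if (is.factor(truth)) levels(truth) else unique(truth)
  truth <- as.character(truth); pred <- as.character(pred)
  unknown <- setdiff(unique(c(truth, pred)), families)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  n <- length(truth)
  tab <- table(factor(truth, levels = families),
               factor(pred, levels = families))
  tp <- diag(tab)
  fn <- rowSums(tab) - tp
  fp <- colSums(tab) - tp
  tn <- n - tp - fn - fp
  counts <- cbind(TP = as.integer(tp), TN = as.integer(tn),
                  FP = as.integer(fp), FN = as.integer(fn))
  rownames(counts) <- families
  new("ConfusionCounts", counts = counts, n = as.integer(n))
}

#' Classification metrics report
#'
#' Holds accuracy, sensitivity, precision and F1 in \code{[0, 1]},
#' together with the averaging mode, the plain correct/total overall
#' accuracy, and the per-class table.
#'
#' @slot accuracy,sensitivity,precision,f1 Averaged metric values.
#' @slot averaging \code{"macro"} or \code{"micro"}.
#' @slot overallAccuracy Correct predictions / total predictions.
#' @slot perClass Data frame of per-class metrics.
#' @slot zeroDenominator Classes where a metric denominator was zero (the
#'   metric was reported as 0 for those classes).
#' @export
setClass("MetricsReport",
  slots = c(accuracy = "numeric", sensitivity = "numeric",
            precision = "numeric", f1 = "numeric", averaging = "character",
            overallAccuracy = "numeric", perClass = "data.frame",
            zeroDenominator = "character"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (%s): accuracy %.4f, sensitivity %.4f, precision %.4f, F1 %.4f\n",
    object@averaging, object@accuracy, object@sensitivity,
    object@precision, object@f1))
  cat(sprintf("  overall accuracy (correct/total): %.4f\n",
              object@overallAccuracy))
})

#' Compute the evaluation metrics from confusion counts
#'
#' Per class (one-vs-rest): accuracy \code{(TP + TN) / (TP + FP + FN +
#' TN)}, sensitivity \code{TP / (TP + FN)}, precision \code{TP / (TP +
#' FP)}, F1 \code{2 TP / (2 TP + FP + FN)} (the harmonic mean of
#' precision and sensitivity). Macro averaging takes the unweighted mean
#' over classes; micro averaging pools the counts first. A zero
#' denominator yields 0 for that class's metric, with the class recorded
#' in the report's \code{zeroDenominator} slot and a warning.
#'
#' @param cc A \code{\linkS4class{ConfusionCounts}}.
#' @param averaging \code{"macro"} (default) or \code{"micro"}.
#' @return A \code{\linkS4class{MetricsReport}}.
#' @examples
#' cc <- confusionCounts(c("a", "b"), c("a", "b"))
#' classificationMetrics(cc)
#' @export
classificationMetrics <- function(cc, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  stopifnot(is(cc, "ConfusionCounts"))
  m <- cc@counts
  safeDiv <- function(num, den) ifelse(den == 0, 0, num / den)
  zero <- character()
  if (any(m[, "TP"] + m[, "FN"] == 0) || any(m[, "TP"] + m[, "FP"] == 0) ||
      any(2 * m[, "TP"] + m[, "FP"] + m[, "FN"] == 0)) {
    zero <- rownames(m)[(m[, "TP"] + m[, "FN"] == 0) |
                          (m[, "TP"] + m[, "FP"] == 0) |
                          (2 * m[, "TP"] + m[, "FP"] + m[, "FN"] == 0)]
    warning("zero denominator for class(es): ",
            paste(zero, collapse = ", "), "; metric reported as 0")
  }
  perClass <- data.frame(
    class = rownames(m),
    accuracy = (m[, "TP"] + m[, "TN"]) / cc@n,
    sensitivity = safeDiv(m[, "TP"], m[, "TP"] + m[, "FN"]),
    precision = safeDiv(m[, "TP"], m[, "TP"] + m[, "FP"]),
    f1 = safeDiv(2 * m[, "TP"], 2 * m[, "TP"] + m[, "FP"] + m[, "FN"]),
    row.names = NULL, stringsAsFactors = FALSE)
  overall <- sum(m[, "TP"]) / cc@n
  if (averaging == "macro") {
    vals <- colMeans(perClass[, c("accuracy", "sensitivity", "precision",
                                  "f1")])
  } else {
    s <- colSums(m)
    vals <- c(accuracy = (s[["TP"]] + s[["TN"]]) /
                (s[["TP"]] + s[["TN"]] + s[["FP"]] + s[["FN"]]),
              sensitivity = safeDiv(s[["TP"]], s[["TP"]] + s[["FN"]]),
              precision = safeDiv(s[["TP"]], s[["TP"]] + s[["FP"]]),
              f1 = safeDiv(2 * s[["TP"]],
                           2 * s[["TP"]] + s[["FP"]] + s[["FN"]]))
  }
  new("MetricsReport",
      accuracy = unname(vals[["accuracy"]]),
      sensitivity = unname(vals[["sensitivity"]]),
      precision = unname(vals[["precision"]]),
      f1 = unname(vals[["f1"]]),
      averaging = averaging, overallAccuracy = overall,
      perClass = perClass, zeroDenominator = zero)
}

#' Write a metrics report as a flat TSV
#'
#' Emits rows (metric, class, value): the averaged metrics with class
#' \code{"<macro>"} / \code{"<micro>"}, the overall accuracy with class
#' \code{"<overall>"}, and every per-class value.
#'
#' @param report A \code{\linkS4class{MetricsReport}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  avg <- paste0("<", report@averaging, ">")
  rows <- rbind(
    data.frame(metric = c("accuracy", "sensitivity", "precision", "f1"),
               class = avg,
               value = c(report@accuracy, report@sensitivity,
                         report@precision, report@f1)),
    data.frame(metric = "accuracy", class = "<overall>",
               value = report@overallAccuracy),
    do.call(rbind, lapply(c("accuracy", "sensitivity", "precision", "f1"),
      function(mname) data.frame(metric = mname,
                                 class = report@perClass$class,
                                 value = report@perClass[[mname]]))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation matrix of per-family F1 scores across folds
#'
#' Pearson correlation between the F1-score columns of a folds x
#' families matrix, as used to study which families succeed or fail
#' together across cross-validation folds. The result is symmetric with
#' unit diagonal; a zero-variance column has undefined correlations,
#' reported as \code{NA} off the diagonal.
#'
#' @param perFoldF1 Numeric matrix, folds x families (>= 3 folds),
#'   column names = family labels.
#' @return families x families correlation matrix.
#' @export
f1CorrelationMatrix <- function(perFoldF1) {
  perFoldF1 <- as.matrix(perFoldF1)
  if (nrow(perFoldF1) < 3L)
    stop("at least 3 folds are required for a correlation matrix")
  sds <- apply(perFoldF1, 2L, stats::sd)
  out <- suppressWarnings(stats::cor(perFoldF1, method = "pearson"))
  out[sds == 0, ] <- NA_real_
  out[, sds == 0] <- NA_real_
  diag(out) <- 1
  out
}
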