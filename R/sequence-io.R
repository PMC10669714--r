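#' Labeled set of RNA sequences
#'
#' An \code{RNAFamilySet} holds noncoding RNA sequences together with the
#' family each sequence belongs to. Sequences are stored as a
#' \code{\link[Biostrings]{RNAStringSet}} whose names are the record ids;
#' the family assignment is a factor whose levels form the ordered family
#' vocabulary of the dataset.
#'
#' Invariants enforced by the validity method: ids are unique and
#' non-empty, sequences are non-empty and contain only A, C, G, U, and the
#' family factor has one entry per sequence with no unused duplicate
#' levels.
#'
#' @slot sequences A \code{\link[Biostrings]{RNAStringSet}}; names are ids.
#' @slot family A factor of length \code{length(sequences)}.
#'
#' @seealso \code{\link{readFamilyFasta}}, \code{\link{generateRfamLike}}
#' @export
setClass("RNAFamilySet",
  slots = c(sequences = "RNAStringSet", family = "factor"))

setValidity("RNAFamilySet", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, "every sequence must have a non-empty id (name)")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicated ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@family) != n)
    msgs <- c(msgs, "family must have one entry per sequence")
  if (n > 0L) {
    if (any(Biostrings::width(object@sequences) == 0L))
      msgs <- c(msgs, "empty sequences are not allowed")
    freq <- Biostrings::alphabetFrequency(object@sequences)
    other <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "U"), drop = FALSE])
    if (any(other > 0L))
      msgs <- c(msgs, sprintf(
        "non-ACGU characters in record(s): %s",
        paste(head(ids[other > 0L], 5L), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an RNAFamilySet from character data
#'
#' Residues are normalized on ingest: lower case is folded to upper case
#' and DNA-style \code{T} is converted to \code{U}. Any other character
#' (including IUPAC ambiguity codes) is rejected with an error naming the
#' offending record and position.
#'
#' @param sequences Character vector of RNA (or DNA) sequences.
#' @param family Character or factor of family labels, one per sequence.
#' @param ids Character vector of unique record ids (defaults to the names
#'   of \code{sequences}).
#' @param familyLevels Optional ordered family vocabulary; defaults to the
#'   unique labels in order of first appearance.
#' @return An \code{\linkS4class{RNAFamilySet}}.
#' @examples
#' x <- RNAFamilySet(c(s1 = "ACGT", s2 = "gguu"), c("tRNA", "IRES"))
#' as.character(sequences(x))
#' @export
RNAFamilySet <- function(sequences, family, ids = names(sequences),
                         familyLevels = NULL) {
  force(ids)
  sequences <- as.character(sequences)
  if (is.null(ids))
    ids <- paste0("seq", seq_along(sequences))
  norm <- chartr("acgut", "ACGUU", sequences)
  norm <- chartr("T", "U", toupper(norm))
  bad <- regexpr("[^ACGU]", norm)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("record '%s' has a non-ACGU character at position %d",
                 ids[i], bad[i]))
  }
  if (is.null(familyLevels))
    familyLevels <- unique(as.character(family))
  fam <- factor(as.character(family), levels = familyLevels)
  if (anyNA(fam)) {
    i <- which(is.na(fam))[1L]
    stop(sprintf("record '%s' has unknown family label '%s'",
                 ids[i], as.character(family)[i]))
  }
  seqs <- Biostrings::RNAStringSet(norm)
  names(seqs) <- ids
  new("RNAFamilySet", sequences = seqs, family = fam)
}

#' @describeIn RNAFamilySet-class Number of records.
#' @param x An \code{RNAFamilySet}.
#' @export
setMethod("length", "RNAFamilySet", function(x) length(x@sequences))

#' Accessors for RNAFamilySet
#'
#' \code{sequences} returns the \code{RNAStringSet}; \code{seqIds} the
#' record ids; \code{familyOf} the per-record family factor;
#' \code{familyLevels} the ordered family vocabulary.
#'
#' @param x An \code{\linkS4class{RNAFamilySet}}.
#' @return See the individual descriptions.
#' @name RNAFamilySet-accessors
NULL

#' @rdname RNAFamilySet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname RNAFamilySet-accessors
#' @export
setMethod("sequences", "RNAFamilySet", function(x) x@sequences)

#' @rdname RNAFamilySet-accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))
#' @rdname RNAFamilySet-accessors
#' @export
setMethod("seqIds", "RNAFamilySet", function(x) names(x@sequences))

#' @rdname RNAFamilySet-accessors
#' @export
setGeneric("familyOf", function(x) standardGeneric("familyOf"))
#' @rdname RNAFamilySet-accessors
#' @export
setMethod("familyOf", "RNAFamilySet", function(x) x@family)

#' @rdname RNAFamilySet-accessors
#' @export
setGeneric("familyLevels", function(x) standardGeneric("familyLevels"))
#' @rdname RNAFamilySet-accessors
#' @export
setMethod("familyLevels", "RNAFamilySet", function(x) levels(x@family))

#' @describeIn RNAFamilySet-class Subset records by index, id or logical.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "RNAFamilySet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("RNAFamilySet", sequences = x@sequences[i],
      family = x@family[if (is.logical(i)) which(i) else i])
})

setMethod("show", "RNAFamilySet", function(object) {
  cat(sprintf("RNAFamilySet with %d sequences in %d families\n",
              length(object), nlevels(object@family)))
  tab <- table(object@family)
  cat("  families:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  w <- Biostrings::width(object@sequences)
  if (length(w))
    cat(sprintf("  lengths: %d-%d nt (median %d)\n",
                min(w), max(w), as.integer(median(w))))
})

#' Combine several RNAFamilySets into one dataset
#'
#' Family levels are ordered by first appearance across the inputs.
#'
#' @param sets A list of \code{\linkS4class{RNAFamilySet}} objects with
#'   globally unique ids.
#' @return A single \code{\linkS4class{RNAFamilySet}}.
#' @export
combineFamilySets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  seqs <- unlist(lapply(sets, function(s) as.character(sequences(s))))
  ids <- unlist(lapply(sets, seqIds))
  fam <- unlist(lapply(sets, function(s) as.character(familyOf(s))))
  RNAFamilySet(seqs, fam, ids = ids, familyLevels = unique(fam))
}

#' Read a labeled RNA FASTA file
#'
#' Sequences are read with \pkg{Biostrings}; residues are normalized
#' (upper case, \code{T} to \code{U}) and validated against the
#' \code{\{A,C,G,U\}} alphabet. Family labels come either from the FASTA
#' headers, expected as \code{>id|family}, or from a two-column
#' tab-separated file (\code{id<TAB>family}, optional header line).
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @param labels Optional path to a two-column TSV mapping id to family.
#'   When \code{NULL}, labels are parsed from the headers.
#' @param familyLevels Optional ordered family vocabulary.
#' @return An \code{\linkS4class{RNAFamilySet}}.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1|tRNA", "ACGT", ">s2|IRES", "GGUU"), f)
#' readFamilyFasta(f)
#' @export
readFamilyFasta <- function(path, labels = NULL, familyLevels = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L)
    stop("no records in FASTA file '", path, "'")
  headers <- names(seqs)
  if (is.null(labels)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    ids <- vapply(parts, `[`, character(1), 1L)
    fam <- vapply(parts, function(p)
      if (length(p) >= 2L) p[[2L]] else NA_character_, character(1))
    if (anyNA(fam))
      stop(sprintf(
        "record '%s' has no '|family' field in its header and no label table was given",
        ids[which(is.na(fam))[1L]]))
  } else {
    tab <- read.delim(labels, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 2L)
      stop("label table must have two tab-separated columns: id, family")
    if (identical(tolower(as.character(tab[1L, 1L])), "id"))
      tab <- tab[-1L, , drop = FALSE]
    ids <- vapply(strsplit(headers, "[ |]"), `[`, character(1), 1L)
    fam <- tab[[2L]][match(ids, as.character(tab[[1L]]))]
    if (anyNA(fam))
      stop(sprintf("record '%s' is missing from the label table",
                   ids[which(is.na(fam))[1L]]))
  }
  ids <- trimws(ids)
  RNAFamilySet(as.character(seqs), trimws(as.character(fam)), ids = ids,
               familyLevels = familyLevels)
}

#' Write a labeled RNA FASTA file
#'
#' With \code{labels = NULL} the family is embedded in the header as
#' \code{>id|family}; otherwise headers carry the id alone and a
#' two-column TSV (id, family) is written to \code{labels}.
#' \code{readFamilyFasta} inverts either form.
#'
#' @param x An \code{\linkS4class{RNAFamilySet}}.
#' @param path Output FASTA path.
#' @param labels Optional path for a companion label TSV.
#' @return \code{path}, invisibly.
#' @export
writeFamilyFasta <- function(x, path, labels = NULL) {
  stopifnot(is(x, "RNAFamilySet"))
  seqs <- x@sequences
  if (is.null(labels)) {
    names(seqs) <- paste0(seqIds(x), "|", as.character(familyOf(x)))
  } else {
    write.table(
      data.frame(id = seqIds(x), family = as.character(familyOf(x))),
      labels, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Stratified cross-validation fold plan
#'
#' Assigns every record to exactly one of \code{nFolds} folds,
#' stratified by family: within each family the records are shuffled with
#' a seeded RNG and dealt round-robin, so per-family counts across folds
#' differ by at most one. Fold indices run from 1 to \code{nFolds}.
#'
#' @slot nFolds Number of folds.
#' @slot assignments Named integer vector mapping record id to fold.
#' @slot seed The seed the plan was built with.
#' @export
setClass("FoldPlan",
  slots = c(nFolds = "integer", assignments = "integer", seed = "integer"))

setValidity("FoldPlan", function(object) {
  a <- object@assignments
  if (is.null(names(a))) return("assignments must be named by record id")
  if (any(a < 1L | a > object@nFolds))
    return("fold indices must lie in 1..nFolds")
  TRUE
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d records in %d folds (seed %d)\n",
              length(object@assignments), object@nFolds, object@seed))
  print(table(fold = object@assignments))
})

#' @rdname makeFolds
#' @export
setGeneric("foldAssignments", function(plan) standardGeneric("foldAssignments"))
#' @rdname makeFolds
#' @export
setMethod("foldAssignments", "FoldPlan", function(plan) plan@assignments)

#' Build a stratified k-fold plan
#'
#' Within every family the member ids are shuffled using a seeded RNG and
#' dealt round-robin over the folds (with a per-family starting offset so
#' no fold systematically collects the remainders). The result is
#' deterministic given the dataset and seed, folds are pairwise disjoint
#' and cover the dataset, and for every family the fold counts differ by
#' at most one.
#'
#' @param x An \code{\linkS4class{RNAFamilySet}}.
#' @param nFolds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A \code{\linkS4class{FoldPlan}}.
#' @examples
#' x <- generateRfamLike(seed = 1, scale = 0.02)
#' plan <- makeFolds(x, nFolds = 2, seed = 1)
#' table(foldAssignments(plan))
#' @export
makeFolds <- function(x, nFolds, seed) {
  stopifnot(is(x, "RNAFamilySet"))
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  fam <- familyOf(x)
  counts <- table(fam)
  small <- names(counts)[counts < nFolds]
  if (length(small))
    stop(sprintf("family '%s' has %d members, fewer than nFolds = %d",
                 small[1L], counts[[small[1L]]], nFolds))
  ids <- seqIds(x)
  assignments <- integer(length(ids))
  names(assignments) <- ids
  withSeed(seed, {
    for (gi in seq_along(levels(fam))) {
      g <- levels(fam)[gi]
      members <- ids[fam == g]
      shuffled <- sample(members)
      offset <- (gi - 1L) %% nFolds
      assignments[shuffled] <-
        ((seq_along(shuffled) - 1L + offset) %% nFolds) + 1L
    }
  })
  new("FoldPlan", nFolds = nFolds, assignments = assignments,
      seed = as.integer(seed))
}

#' Write / read a fold plan as a two-column table
#'
#' @param plan A \code{\linkS4class{FoldPlan}}.
#' @param path Path to a TSV with columns id, fold.
#' @return \code{writeFoldPlan}: \code{path} invisibly.
#' @export
writeFoldPlan <- function(plan, path) {
  write.table(
    data.frame(id = names(plan@assignments), fold = plan@assignments),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
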