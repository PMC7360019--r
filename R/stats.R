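# Corpus statistics, inter-annotator agreement, and splits.

#' Tag distribution of a tagged corpus
#'
#' Tallies `B`/`I`/`O` tags and reports percentages rounded to one decimal.
#' Accepts either a list of [TaggedSequence-class] objects or a named count
#' vector (so published tag-count tables can be summarized directly).
#'
#' @param x list of [TaggedSequence-class] objects, or named numeric counts.
#' @return a [TagDistribution-class].
#' @examples
#' tagDistribution(c(B = 23648, I = 200272, O = 91877))
#' @export
tagDistribution <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    stopifnot(!is.null(names(counts)), all(names(counts) %in% .TAGS))
  } else {
    if (!length(x)) stop("empty corpus")
    allTags <- unlist(lapply(x, tags))
    counts <- as.numeric(table(factor(allTags, .TAGS)))
    names(counts) <- .TAGS
  }
  total <- sum(counts)
  if (total <= 0) stop("no tags to tally")
  new("TagDistribution", counts = counts,
      percentages = round(100 * counts / total, 1))
}

.classifyTermination <- function(sentenceText) {
  stripped <- sub(paste0("[", .WS_CLASS, "]+$"), "", sentenceText, perl = TRUE)
  last <- substring(stripped, nchar(stripped), nchar(stripped))
  ifelse(last == ".", "period",
  ifelse(last == "!", "exclamation",
  ifelse(last == "?", "question",
  ifelse(last == ";", "semicolon",
  ifelse(last == ":", "colon",
  ifelse(last == "\"" | last == "'", "quotation", "none"))))))
}

#' Sentence termination-type statistics
#'
#' Classifies every "Sentence" annotation by its final non-whitespace
#' character (`.` `!` `?` `;` `:` quotation marks, anything else counting as
#' unterminated) and reports counts with percentages rounded to one decimal.
#' A named count vector over the termination types is also accepted, so the
#' percentage column of a published count table can be recomputed.
#'
#' @param x list of [AnnotatedDocument-class] objects, or named numeric
#'   counts over the termination types.
#' @return a [TerminationStats-class].
#' @export
terminationStats <- function(x) {
  if (is.numeric(x)) {
    stopifnot(!is.null(names(x)), all(names(x) %in% .TERM_TYPES))
    counts <- setNames(numeric(length(.TERM_TYPES)), .TERM_TYPES)
    counts[names(x)] <- x
  } else {
    sentTexts <- unlist(lapply(x, function(d) {
      ann <- annotations(d)
      ann$text[ann$label == "Sentence"]
    }))
    if (!length(sentTexts)) stop("no Sentence annotations")
    cls <- .classifyTermination(sentTexts)
    counts <- as.numeric(table(factor(cls, .TERM_TYPES)))
    names(counts) <- .TERM_TYPES
  }
  new("TerminationStats", counts = counts,
      percentages = round(100 * counts / sum(counts), 1))
}

#' Cohen's kappa between two tag sequences
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} where
#' \eqn{p_e} comes from the marginal label frequencies of each rater.
#' Positions where either sequence carries an excluded label are dropped
#' first (pass `exclude = "O"` to score agreement after removing items either
#' annotator marked un-evaluable).
#'
#' @param a,b equal-length character vectors of labels.
#' @param exclude labels to exclude (positions dropped when present in
#'   either sequence).
#' @return kappa in `[-1, 1]`; `NA` with a warning when chance agreement is 1
#'   (kappa undefined).
#' @export
cohensKappa <- function(a, b, exclude = character()) {
  if (length(a) != length(b)) stop("sequences must have equal length")
  keep <- !(a %in% exclude | b %in% exclude)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no positions left after exclusion")
  labs <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pa <- as.numeric(table(factor(a, labs))) / length(a)
  pb <- as.numeric(table(factor(b, labs))) / length(b)
  pe <- sum(pa * pb)
  if (abs(1 - pe) < 1e-12) {
    warning("chance agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Split a corpus into train/validation(/test) document sets
#'
#' Document-level (never token-level) splitting, so no note leaks across
#' splits. `"cv_only"` shuffles the documents and assigns 80% to training and
#' 20% to validation. `"cv_plus_holdout"` first holds out 50% as an unseen
#' test set, then splits the remainder 80/20.
#'
#' @param docs list of documents (any type; split at the list level).
#' @param scheme `"cv_only"` or `"cv_plus_holdout"`.
#' @param seed integer; the split is deterministic given the seed.
#' @return list with elements `train`, `validation`, `test` (empty for
#'   `"cv_only"`).
#' @export
splitCorpus <- function(docs, scheme = c("cv_only", "cv_plus_holdout"), seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(docs)
  ord <- .withSeed(seed, sample.int(n))
  if (scheme == "cv_only") {
    nTrain <- floor(0.8 * n)
    if (nTrain < 1L || n - nTrain < 1L) stop("fewer documents than splits")
    list(train = docs[ord[seq_len(nTrain)]],
         validation = docs[ord[(nTrain + 1L):n]],
         test = docs[integer()])
  } else {
    nTest <- floor(n / 2)
    rest <- n - nTest
    nTrain <- floor(0.8 * rest)
    if (nTest < 1L || nTrain < 1L || rest - nTrain < 1L)
      stop("fewer documents than splits")
    list(train = docs[ord[(nTest + 1L):(nTest + nTrain)]],
         validation = docs[ord[(nTest + nTrain + 1L):n]],
         test = docs[ord[seq_len(nTest)]])
  }
}
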