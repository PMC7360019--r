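#' @import methods
NULL

.emptyAnnotations <- function() {
  data.frame(label = character(), begin = integer(), end = integer(),
             text = character(), stringsAsFactors = FALSE)
}

#' AnnotatedDocument: note text plus gold standoff spans
#'
#' Holds the plain text of one clinical note together with its "Sentence" and
#' "Unsure" span annotations (the BRAT standoff view). Offsets are 0-based
#' character offsets, half-open: a span covers `substr(text, begin + 1, end)`.
#'
#' @slot docId document identifier.
#' @slot text full note text (UTF-8, newlines normalized to `"\n"`).
#' @slot annotations `data.frame` with columns `label` (`"Sentence"` or
#'   `"Unsure"`), `begin`, `end` and `text` (the covered string).
#' @export
setClass("AnnotatedDocument",
  representation(docId = "character", text = "character",
                 annotations = "data.frame"))

setValidity("AnnotatedDocument", function(object) {
  msg <- character()
  if (length(object@docId) != 1L) msg <- c(msg, "docId must be length 1")
  if (length(object@text) != 1L) msg <- c(msg, "text must be length 1")
  ann <- object@annotations
  need <- c("label", "begin", "end", "text")
  if (!all(need %in% names(ann))) {
    msg <- c(msg, "annotations needs columns label, begin, end, text")
  } else if (nrow(ann) > 0L) {
    if (!all(ann$label %in% c("Sentence", "Unsure")))
      msg <- c(msg, "annotation labels must be Sentence or Unsure")
    if (any(ann$end <= ann$begin)) msg <- c(msg, "spans must have end > begin")
    if (any(ann$begin < 0) || any(ann$end > nchar(object@text)))
      msg <- c(msg, "spans must lie within the document text")
    for (lab in unique(ann$label)) {
      s <- ann[ann$label == lab, , drop = FALSE]
      s <- s[order(s$begin), , drop = FALSE]
      if (nrow(s) > 1L && any(s$begin[-1L] < s$end[-nrow(s)]))
        msg <- c(msg, sprintf("overlapping %s spans", lab))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedDocument
#'
#' @param docId document identifier.
#' @param text note text.
#' @param annotations data.frame of spans (columns `label`, `begin`, `end`,
#'   and optionally `text`; missing `text` is filled from the document).
#' @return An [AnnotatedDocument-class] object.
#' @export
annotatedDocument <- function(docId, text, annotations = .emptyAnnotations()) {
  text <- enc2utf8(text)
  if (nrow(annotations) > 0L) {
    if (is.null(annotations$text))
      annotations$text <- substring(text, annotations$begin + 1L, annotations$end)
    annotations <- annotations[order(annotations$begin, annotations$end), ,
                               drop = FALSE]
    rownames(annotations) <- NULL
    annotations$begin <- as.integer(annotations$begin)
    annotations$end <- as.integer(annotations$end)
  } else {
    annotations <- .emptyAnnotations()
  }
  new("AnnotatedDocument", docId = docId, text = text,
      annotations = annotations)
}

#' TaggedSequence: tokens paired with B/I/O tags
#'
#' The unit of training and evaluation: one document's tokens, each carrying a
#' `B` (sentence-initial), `I` (sentence-internal) or `O` (un-evaluable) tag.
#' The raw text is retained because the tagger's character context windows are
#' drawn from it.
#'
#' @slot docId document identifier.
#' @slot text the source document text.
#' @slot tokens `data.frame` with columns `text`, `begin`, `end` as produced
#'   by [tokenizeText()].
#' @slot tags character vector over `B`/`I`/`O`, one per token.
#' @export
setClass("TaggedSequence",
  representation(docId = "character", text = "character",
                 tokens = "data.frame", tags = "character"))

setValidity("TaggedSequence", function(object) {
  msg <- character()
  if (nrow(object@tokens) != length(object@tags))
    msg <- c(msg, "one tag per token required")
  if (length(object@tags) && !all(object@tags %in% .TAGS))
    msg <- c(msg, "tags must be B, I or O")
  if (length(msg)) msg else TRUE
})

#' SymbolVocab: symbol-to-id mapping
#'
#' Maps symbols (characters, marker symbols, or words) to contiguous 0-based
#' integer ids. Id 0 is always the padding symbol; unknown symbols map to the
#' reserved `<unk>` id.
#'
#' @slot symbols character vector; the symbol at position `i` has id `i - 1`.
#' @export
setClass("SymbolVocab", representation(symbols = "character"))

setValidity("SymbolVocab", function(object) {
  msg <- character()
  if (length(object@symbols) < 2L) msg <- c(msg, "vocab needs at least PAD and UNK")
  if (anyDuplicated(object@symbols)) msg <- c(msg, "symbols must be unique")
  if (length(object@symbols) && object@symbols[1L] != "<pad>")
    msg <- c(msg, "id 0 must be <pad>")
  if (!"<unk>" %in% object@symbols) msg <- c(msg, "vocab must contain <unk>")
  if (length(msg)) msg else TRUE
})

#' TagDistribution: tag counts and percentages
#'
#' @slot counts named numeric of tag counts.
#' @slot percentages named numeric, each `round(100 * count / total, 1)`.
#' @export
setClass("TagDistribution",
  representation(counts = "numeric", percentages = "numeric"))

#' TerminationStats: sentence termination-type counts and percentages
#'
#' @slot counts named numeric over termination types (`period`, `exclamation`,
#'   `question`, `semicolon`, `colon`, `quotation`, `none`).
#' @slot percentages named numeric, one decimal.
#' @export
setClass("TerminationStats",
  representation(counts = "numeric", percentages = "numeric"))

#' EvalReport: tag-level scores with O-exclusion
#'
#' Precision/recall/F1 and confusion counts for the `B` and `I` tags after
#' removing every position whose gold tag is `O`.
#'
#' @slot precision,recall,f1 named numeric over `B` and `I`.
#' @slot tp,fp,fn named numeric confusion counts over `B` and `I`.
#' @slot nEvaluated number of evaluated (non-O) positions.
#' @export
setClass("EvalReport",
  representation(precision = "numeric", recall = "numeric", f1 = "numeric",
                 tp = "numeric", fp = "numeric", fn = "numeric",
                 nEvaluated = "numeric"))

#' DomainProfile: parameters of one synthetic note domain
#'
#' Describes how the synthetic generator writes notes for one domain: the
#' sentence termination-type mix, the rate of un-evaluable numeric blocks,
#' abbreviation density, the word pool, and formatting habits (hard wrapping,
#' bullets, lowercase fragment starts, ...).
#'
#' @slot name profile name.
#' @slot terminationMix named numeric over the seven termination types,
#'   summing to 1.
#' @slot unsureRate per-line probability of starting an "Unsure" numeric block.
#' @slot abbrevRate per-sentence probability of containing a dotted
#'   abbreviation.
#' @slot vocabulary word pool for prose.
#' @slot formatting list of formatting habits (see [domainProfile()]).
#' @export
setClass("DomainProfile",
  representation(name = "character", terminationMix = "numeric",
                 unsureRate = "numeric", abbrevRate = "numeric",
                 vocabulary = "character", formatting = "list"))

setValidity("DomainProfile", function(object) {
  msg <- character()
  if (!setequal(names(object@terminationMix), .TERM_TYPES))
    msg <- c(msg, "terminationMix must name all seven termination types")
  if (abs(sum(object@terminationMix) - 1) > 1e-9)
    msg <- c(msg, "terminationMix must sum to 1")
  if (any(object@terminationMix < 0)) msg <- c(msg, "terminationMix must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SbdModel: the char-CNN + bi-LSTM sentence boundary tagger
#'
#' Bundles the architecture configuration, the character and word
#' vocabularies, optionally a pretrained word-vector table, the network
#' parameters, and the training log.
#'
#' @slot config configuration list from [modelConfig()].
#' @slot charVocab,wordVocab [SymbolVocab-class] objects.
#' @slot wordVectors a word-vector table from [loadWordVectors()], or `NULL`
#'   (tokens then enter the network through the character pathway alone).
#' @slot params list of parameter tensors.
#' @slot trainLog list with per-epoch losses, best epoch, seed.
#' @export
setClass("SbdModel",
  representation(config = "list", charVocab = "SymbolVocab",
                 wordVocab = "SymbolVocab", wordVectors = "ANY",
                 params = "list", trainLog = "list"))

#' SbdEnsembleModel: stacking ensemble of a frozen base and a correction tower
#'
#' The domain-adaptation stacking ensemble: the contextual word
#' representations of a frozen source-domain network are summed with those of
#' a freshly trained target-domain tower before a shared sigmoid prediction
#' layer.
#'
#' @slot base the frozen source-domain [SbdModel-class].
#' @slot params parameters of the correction tower and the shared prediction
#'   layer.
#' @slot config configuration list.
#' @slot trainLog training log of the ensemble fit.
#' @export
setClass("SbdEnsembleModel",
  representation(base = "SbdModel", params = "list", config = "list",
                 trainLog = "list"))
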