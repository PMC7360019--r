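# Symbol vocabularies for the character and word pathways.

.SPECIALS <- c(PAD = "<pad>", UNK = "<unk>", PREV_END = "<prev_end>",
               NEXT_BEGIN = "<next_begin>", WORD_BEGIN = "<word_begin>",
               WORD_END = "<word_end>", DOC_BEGIN = "<doc_begin>",
               DOC_END = "<doc_end>")

.freqOrder <- function(items) {
  tb <- table(items)
  # frequency descending, ties broken lexicographically: deterministic
  names(tb)[order(-as.numeric(tb), names(tb))]
}

.textOf <- function(x) {
  if (is.character(x)) return(x)
  vapply(x, function(d) {
    if (is(d, "AnnotatedDocument") || is(d, "TaggedSequence")) noteText(d)
    else stop("expected documents, tagged sequences or character texts")
  }, character(1))
}

#' Build the character vocabulary
#'
#' Collects every character observed in the corpus texts plus the marker
#' symbols used by the character context window (`<pad>`, `<unk>`,
#' `<prev_end>`, `<next_begin>`, `<word_begin>`, `<word_end>`, `<doc_begin>`,
#' `<doc_end>`). Observed characters are ordered by frequency (ties
#' lexicographic), so the mapping is deterministic; id 0 is `<pad>`.
#'
#' @param x list of [AnnotatedDocument-class]/[TaggedSequence-class] objects,
#'   or a character vector of document texts.
#' @return a [SymbolVocab-class].
#' @export
buildCharVocab <- function(x) {
  texts <- .textOf(x)
  if (!length(texts) || !any(nzchar(texts))) stop("empty corpus")
  chars <- unlist(strsplit(texts, "", fixed = TRUE), use.names = FALSE)
  ordered <- .freqOrder(chars)
  ordered <- setdiff(ordered, .SPECIALS)
  new("SymbolVocab", symbols = c(unname(.SPECIALS), ordered))
}

#' Build the word vocabulary
#'
#' Word symbols are lowercased token texts, ordered by corpus frequency
#' (ties lexicographic), after `<pad>` (id 0) and `<unk>`.
#'
#' @param x list of [TaggedSequence-class] objects, or a character vector of
#'   token texts.
#' @return a [SymbolVocab-class].
#' @export
buildWordVocab <- function(x) {
  words <- if (is.character(x)) x else
    unlist(lapply(x, function(s) tokens(s)$text), use.names = FALSE)
  if (!length(words)) stop("empty corpus")
  ordered <- .freqOrder(tolower(words))
  ordered <- setdiff(ordered, c("<pad>", "<unk>"))
  new("SymbolVocab", symbols = c("<pad>", "<unk>", ordered))
}

#' Map symbols to integer ids
#'
#' @param vocab a [SymbolVocab-class].
#' @param symbols character vector.
#' @return 0-based integer ids; unseen symbols receive the `<unk>` id.
#' @export
vocabIds <- function(vocab, symbols) {
  i <- match(symbols, vocab@symbols)
  i[is.na(i)] <- match("<unk>", vocab@symbols)
  i - 1L
}

#' Vocabulary size
#' @param vocab a [SymbolVocab-class].
#' @return number of symbols (including `<pad>` and `<unk>`).
#' @export
vocabSize <- function(vocab) length(vocab@symbols)

#' Save / load a vocabulary as JSON
#'
#' The symbol order (and therefore every id) round-trips exactly.
#'
#' @param vocab a [SymbolVocab-class].
#' @param path JSON file path.
#' @return `saveVocab` returns `path` invisibly; `loadVocab` the vocabulary.
#' @export
saveVocab <- function(vocab, path) {
  jsonlite::write_json(list(symbols = vocab@symbols), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname saveVocab
#' @export
loadVocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SymbolVocab", symbols = as.character(obj$symbols))
}
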