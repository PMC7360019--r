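# Character context windows: the raw-text neighborhood each token presents to
# the character CNN, and the fixed windows used by the LR baseline.

#' Character context window of a token
#'
#' Builds the symbol sequence the character CNN reads for one token: the
#' token's own characters enclosed by `<word_begin>`/`<word_end>`, plus up to
#' `contextChars` raw characters from the gap on each side (the characters
#' nearest the token are kept when a gap is longer). Whitespace characters in
#' the gaps are preserved verbatim: document formatting such as line breaks is
#' evidence for boundary decisions. Marker symbols are inserted when the
#' corresponding landmark falls inside the context: `<prev_end>` when the
#' previous token ends within `contextChars` characters of the token,
#' `<next_begin>` symmetrically, and `<doc_begin>`/`<doc_end>` when a document
#' edge does. Markers are not counted against the character budget.
#'
#' @param docText the document string the tokens were produced from.
#' @param tokens token table from [tokenizeText()].
#' @param index token position (1-based).
#' @param contextChars gap budget per side (default 7).
#' @return character vector of symbols.
#' @examples
#' toks <- tokenizeText("Plan")
#' charContext("Plan", toks, 1)
#' @export
charContext <- function(docText, tokens, index, contextChars = 7L) {
  n <- nrow(tokens)
  if (index < 1L || index > n) stop("token index out of range")
  b <- tokens$begin[index]
  e <- tokens$end[index]
  nc <- nchar(docText)

  gapStart <- if (index == 1L) 0L else tokens$end[index - 1L]
  gapLen <- b - gapStart
  take <- min(gapLen, contextChars)
  leftChars <- if (take > 0L)
    strsplit(substr(docText, b - take + 1L, b), "", fixed = TRUE)[[1L]]
  else character()
  left <- if (gapLen <= contextChars) {
    c(if (index == 1L) .SPECIALS[["DOC_BEGIN"]] else .SPECIALS[["PREV_END"]],
      leftChars)
  } else leftChars

  gapEnd <- if (index == n) nc else tokens$begin[index + 1L]
  gapLenR <- gapEnd - e
  takeR <- min(gapLenR, contextChars)
  rightChars <- if (takeR > 0L)
    strsplit(substr(docText, e + 1L, e + takeR), "", fixed = TRUE)[[1L]]
  else character()
  right <- if (gapLenR <= contextChars) {
    c(rightChars,
      if (index == n) .SPECIALS[["DOC_END"]] else .SPECIALS[["NEXT_BEGIN"]])
  } else rightChars

  wordChars <- strsplit(substr(docText, b + 1L, e), "", fixed = TRUE)[[1L]]
  c(left, .SPECIALS[["WORD_BEGIN"]], wordChars, .SPECIALS[["WORD_END"]], right)
}

# Contexts for every token of a document (list of symbol vectors).
.charContextsAll <- function(docText, tokens, contextChars = 7L) {
  lapply(seq_len(nrow(tokens)), function(i)
    charContext(docText, tokens, i, contextChars))
}

#' Character-window features for the LR baseline
#'
#' Encodes the fixed-size input of the logistic-regression baseline: four
#' 7-character windows per token — the 7 characters before the token, the
#' first 7 and last 7 characters of the token, and the 7 characters after it.
#' Short windows are filled with `<pad>`; where a document edge falls inside
#' the before/after window it is marked with `<doc_begin>`/`<doc_end>`.
#'
#' @param docText document string.
#' @param tokens token table from [tokenizeText()].
#' @param index token position (1-based).
#' @param width window width (default 7).
#' @return character vector of `4 * width` symbols
#'   (before, first, last, after).
#' @export
lrBaselineFeatures <- function(docText, tokens, index, width = 7L) {
  n <- nrow(tokens)
  if (index < 1L || index > n) stop("token index out of range")
  b <- tokens$begin[index]
  e <- tokens$end[index]
  nc <- nchar(docText)
  pad <- .SPECIALS[["PAD"]]

  availB <- min(b, width)
  beforeChars <- if (availB > 0L)
    strsplit(substr(docText, b - availB + 1L, b), "", fixed = TRUE)[[1L]]
  else character()
  before <- if (availB < width) {
    c(rep(pad, width - availB - 1L), .SPECIALS[["DOC_BEGIN"]], beforeChars)
  } else beforeChars

  wordChars <- strsplit(substr(docText, b + 1L, e), "", fixed = TRUE)[[1L]]
  wlen <- length(wordChars)
  first <- c(wordChars[seq_len(min(wlen, width))],
             rep(pad, max(0L, width - wlen)))
  last <- c(rep(pad, max(0L, width - wlen)),
            wordChars[seq.int(max(1L, wlen - width + 1L), wlen)])

  availA <- min(nc - e, width)
  afterChars <- if (availA > 0L)
    strsplit(substr(docText, e + 1L, e + availA), "", fixed = TRUE)[[1L]]
  else character()
  after <- if (availA < width) {
    c(afterChars, .SPECIALS[["DOC_END"]], rep(pad, width - availA - 1L))
  } else afterChars

  unname(c(before, first, last, after))
}
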