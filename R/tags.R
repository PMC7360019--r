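# Span-to-tag conversion and CoNLL-style output.

#' Convert gold spans to B/I/O token tags
#'
#' Applies the tagging rule: the first token inside each "Sentence" span is
#' tagged `B`, the remaining tokens of the span `I`, and tokens inside
#' "Unsure" spans `O`. Tokens outside every annotation are also tagged `O`
#' (they are equally un-evaluable, and `O` positions are masked during
#' training and evaluation). A token whose begin offset lies inside a span
#' belongs to that span; where a Sentence and an Unsure span both claim a
#' token, the Unsure label wins (low-confidence regions must not contribute
#' supervised signal) and a message is emitted.
#'
#' @param doc an [AnnotatedDocument-class].
#' @param tokens token table from [tokenizeText()] on `noteText(doc)`;
#'   computed if missing.
#' @return a [TaggedSequence-class].
#' @export
toBioTags <- function(doc, tokens = tokenizeText(noteText(doc))) {
  stopifnot(is(doc, "AnnotatedDocument"))
  n <- nrow(tokens)
  tgs <- rep("O", n)
  ann <- doc@annotations
  sent <- ann[ann$label == "Sentence", , drop = FALSE]
  if (nrow(sent)) {
    sent <- sent[order(sent$begin), , drop = FALSE]
    for (k in seq_len(nrow(sent))) {
      inside <- which(tokens$begin >= sent$begin[k] & tokens$begin < sent$end[k])
      if (length(inside)) {
        tgs[inside[1L]] <- "B"
        if (length(inside) > 1L) tgs[inside[-1L]] <- "I"
      }
    }
  }
  uns <- ann[ann$label == "Unsure", , drop = FALSE]
  if (nrow(uns)) {
    for (k in seq_len(nrow(uns))) {
      inside <- which(tokens$begin >= uns$begin[k] & tokens$begin < uns$end[k])
      if (any(tgs[inside] != "O"))
        message(sprintf("document '%s': %d token(s) overlap both Sentence and Unsure; Unsure wins",
                        doc@docId, sum(tgs[inside] != "O")))
      tgs[inside] <- "O"
    }
  }
  new("TaggedSequence", docId = doc@docId, text = doc@text,
      tokens = tokens, tags = tgs)
}

#' Tag a whole corpus
#'
#' @param docs list of [AnnotatedDocument-class] objects.
#' @return list of [TaggedSequence-class] objects.
#' @export
tagCorpus <- function(docs) lapply(docs, toBioTags)

#' Write tagged sequences in two-column CoNLL style
#'
#' One `token<TAB>tag` line per token, with a blank line between documents.
#'
#' @param seqs list of [TaggedSequence-class] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeConll <- function(seqs, path) {
  out <- unlist(lapply(seqs, function(s) {
    c(paste(s@tokens$text, s@tags, sep = "\t"), "")
  }))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
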