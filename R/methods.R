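# Accessors and show methods.

#' @rdname AnnotatedDocument-class
#' @export
setMethod("docId", "AnnotatedDocument", function(x) x@docId)

#' @rdname TaggedSequence-class
#' @export
setMethod("docId", "TaggedSequence", function(x) x@docId)

#' @rdname AnnotatedDocument-class
#' @export
setMethod("noteText", "AnnotatedDocument", function(x) x@text)

#' @rdname TaggedSequence-class
#' @export
setMethod("noteText", "TaggedSequence", function(x) x@text)

#' @rdname AnnotatedDocument-class
#' @export
setMethod("annotations", "AnnotatedDocument", function(x) x@annotations)

#' @rdname TaggedSequence-class
#' @export
setMethod("tokens", "TaggedSequence", function(x) x@tokens)

#' @rdname TaggedSequence-class
#' @export
setMethod("tags", "TaggedSequence", function(x) x@tags)

setMethod("show", "AnnotatedDocument", function(object) {
  ann <- object@annotations
  cat(sprintf("AnnotatedDocument '%s': %d characters, %d Sentence / %d Unsure spans\n",
              object@docId, nchar(object@text),
              sum(ann$label == "Sentence"), sum(ann$label == "Unsure")))
})

setMethod("show", "TaggedSequence", function(object) {
  tb <- table(factor(object@tags, .TAGS))
  cat(sprintf("TaggedSequence '%s': %d tokens (B=%d I=%d O=%d)\n",
              object@docId, nrow(object@tokens), tb["B"], tb["I"], tb["O"]))
})

setMethod("show", "SymbolVocab", function(object) {
  cat(sprintf("SymbolVocab with %d symbols (id 0 = <pad>)\n",
              length(object@symbols)))
})

setMethod("show", "TagDistribution", function(object) {
  cat("Tag distribution\n")
  for (tg in names(object@counts))
    cat(sprintf("  %s  %10.0f  %5.1f%%\n", tg, object@counts[tg],
                object@percentages[tg]))
  cat(sprintf("  total %8.0f\n", sum(object@counts)))
})

setMethod("show", "TerminationStats", function(object) {
  cat("Sentence termination types\n")
  for (tp in names(object@counts))
    cat(sprintf("  %-12s %8.0f  %5.1f%%\n", tp, object@counts[tp],
                object@percentages[tp]))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d evaluated tokens (gold O excluded)\n",
              object@nEvaluated))
  for (tg in c("B", "I"))
    cat(sprintf("  %s  P=%.3f R=%.3f F1=%.3f  (TP=%d FP=%d FN=%d)\n", tg,
                object@precision[tg], object@recall[tg], object@f1[tg],
                object@tp[tg], object@fp[tg], object@fn[tg]))
})

setMethod("show", "DomainProfile", function(object) {
  mix <- paste(sprintf("%s=%.3f", names(object@terminationMix),
                       object@terminationMix), collapse = " ")
  cat(sprintf("DomainProfile '%s'\n  termination mix: %s\n  unsureRate=%.2f abbrevRate=%.2f, %d vocabulary words\n",
              object@name, mix, object@unsureRate, object@abbrevRate,
              length(object@vocabulary)))
})

setMethod("show", "SbdModel", function(object) {
  cfg <- object@config
  cat(sprintf("SbdModel: char-CNN (%d filters, width %d) + bi-LSTM (%d units/direction)\n",
              cfg$cnnFilters, cfg$cnnWidth, cfg$lstmUnits))
  cat(sprintf("  word dim %d, char dim %d, char vocab %d, %d trainable parameters\n",
              cfg$wordDim, cfg$charDim, length(object@charVocab@symbols),
              parameterCount(object)))
  if (length(object@trainLog))
    cat(sprintf("  trained: best epoch %d, validation loss %.4f\n",
                object@trainLog$bestEpoch, object@trainLog$bestLoss))
  else cat("  untrained\n")
})

setMethod("show", "SbdEnsembleModel", function(object) {
  cat(sprintf("SbdEnsembleModel: frozen base + correction tower, %d trainable parameters total\n",
              parameterCount(object)))
})
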