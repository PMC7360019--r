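#' @rdname AnnotatedDocument-class
#' @param object,x an object.
#' @export
setGeneric("docId", function(x) standardGeneric("docId"))

#' @rdname AnnotatedDocument-class
#' @export
setGeneric("noteText", function(x) standardGeneric("noteText"))

#' @rdname AnnotatedDocument-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname TaggedSequence-class
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))

#' @rdname TaggedSequence-class
#' @export
setGeneric("tags", function(x) standardGeneric("tags"))

#' Number of trainable parameters
#'
#' @param x a model object.
#' @return integer count of trainable scalars (batch-normalization moving
#'   statistics excluded: they are maintained, not optimized).
#' @export
setGeneric("parameterCount", function(x) standardGeneric("parameterCount"))

#' Predict B/I tags for tagged sequences
#'
#' Runs the tagger at inference (dropout off, batch-normalization moving
#' statistics) over each document, windowed into non-overlapping
#' `seqLen`-token windows, and thresholds the per-token boundary probability.
#' `O` is never predicted: un-evaluable positions are handled by masking in
#' training and evaluation, not by the classifier.
#'
#' @param model an [SbdModel-class] or [SbdEnsembleModel-class].
#' @param seqs list of [TaggedSequence-class] objects.
#' @param ... unused.
#' @return list of character vectors over `B`/`I`, one per sequence.
#' @export
setGeneric("predictTags", function(model, seqs, ...) standardGeneric("predictTags"))

#' Per-token boundary probabilities
#'
#' @param model a fitted model.
#' @param seqs list of [TaggedSequence-class] objects.
#' @param ... unused.
#' @return list of numeric probability vectors, one per sequence.
#' @export
setGeneric("predictProbs", function(model, seqs, ...) standardGeneric("predictProbs"))
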