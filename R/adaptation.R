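# Domain adaptation: merged training, continued training, and the stacking
# ensemble.

.checkSplit <- function(corpus) {
  stopifnot(is.list(corpus), all(c("train", "validation") %in% names(corpus)))
  corpus
}

#' Merged training on two corpora
#'
#' Trains a single fresh model on the concatenated training splits of both
#' corpora, validated on the concatenated validation splits. Vocabularies are
#' built on the union, so neither domain's symbols fall to `<unk>`. With an
#' empty second corpus this reduces exactly to training on the first alone.
#'
#' @param corpusA,corpusB lists with elements `train` and `validation`, each
#'   a list of [TaggedSequence-class] objects (`corpusB` may hold empty
#'   lists).
#' @param config configuration from [modelConfig()].
#' @param wordVectors optional word-vector table shared by both domains.
#' @param verbose print per-epoch losses.
#' @return a trained [SbdModel-class].
#' @export
trainMerged <- function(corpusA, corpusB, config = modelConfig(),
                        wordVectors = NULL, verbose = FALSE) {
  .checkSplit(corpusA); .checkSplit(corpusB)
  train <- c(corpusA$train, corpusB$train)
  validation <- c(corpusA$validation, corpusB$validation)
  if (!length(train)) stop("no training documents")
  charVocab <- buildCharVocab(train)
  wordVocab <- buildWordVocab(train)
  model <- sbdModel(charVocab, wordVocab, config, wordVectors)
  trainSbdModel(model, train, validation, verbose = verbose)
}

#' Continued training on a target corpus
#'
#' Resumes optimization of a pretrained network on the target corpus: all
#' weights stay trainable, the optimizer state is reinitialized, and early
#' stopping is monitored on the target validation loss. Target-corpus symbols
#' unseen by the pretrained vocabularies map to `<unk>` (a message reports
#' how many). The returned checkpoint is never worse on the target
#' validation loss than the pretrained weights themselves.
#'
#' @param model a trained [SbdModel-class].
#' @param corpusB list with `train` and `validation` splits of the target
#'   corpus.
#' @param config configuration; defaults to the pretrained model's (pass a
#'   modified copy to change the seed or learning rate).
#' @param verbose print per-epoch losses.
#' @return the adapted [SbdModel-class].
#' @export
continueTraining <- function(model, corpusB, config = model@config,
                             verbose = FALSE) {
  .checkSplit(corpusB)
  chars <- unlist(strsplit(vapply(corpusB$train, noteText, character(1)), "",
                           fixed = TRUE))
  unseen <- sum(!unique(chars) %in% model@charVocab@symbols)
  if (unseen > 0L)
    message(sprintf("%d target-corpus character(s) unseen by the pretrained vocabulary map to <unk>",
                    unseen))
  model@config <- config
  if (!length(corpusB$train) || config$maxEpochs < 1L) return(model)
  trainSbdModel(model, corpusB$train, corpusB$validation,
                initialBest = TRUE, verbose = verbose)
}

#' Stacking-ensemble adaptation
#'
#' Builds the two-network stacking ensemble: the pretrained base network is
#' frozen, a correction tower with identical dimensions is freshly
#' initialized, and the per-token contextual word representations of both
#' towers are summed before a shared, freshly initialized sigmoid prediction
#' layer. Only the correction tower and the shared prediction layer are
#' optimized on the target corpus, so the second network learns corrections
#' to the first. Both towers share the base model's vocabularies; unseen
#' target symbols map to `<unk>`.
#'
#' @param base a trained [SbdModel-class] (left untouched).
#' @param corpusB list with `train` and `validation` splits of the target
#'   corpus.
#' @param config configuration; must match the base model's dimensions.
#' @param freezeBase keep the base tower frozen (the default and the intended
#'   semantics; exposed for ablation).
#' @param verbose print per-epoch losses.
#' @return an [SbdEnsembleModel-class].
#' @export
ensembleStack <- function(base, corpusB, config = base@config,
                          freezeBase = TRUE, verbose = FALSE) {
  .checkSplit(corpusB)
  if (config$lstmUnits != base@config$lstmUnits ||
      config$wordDim != base@config$wordDim ||
      config$charDim != base@config$charDim)
    stop("ensemble tower dimensions must match the base model")
  if (!freezeBase)
    stop("joint fine-tuning of the base tower is not implemented; the base is a fixed reference")
  newParams <- .withSeed(config$seed,
    c(.initTower(config, vocabSize(base@charVocab)),
      list(dense = .initDense(config))))
  classW <- .trainClassWeights(corpusB$train)
  trainEnc <- .encodeCorpus(corpusB$train, base@charVocab, base@wordVectors,
                            config)
  shim <- base
  shim@config <- config
  valBatches <- makeBatches(corpusB$validation, shim, seed = NULL)
  fit <- .fit(newParams, trainEnc, valBatches, config, classW,
              baseParams = base@params, verbose = verbose)
  new("SbdEnsembleModel", base = base, params = fit$params, config = config,
      trainLog = fit$log)
}
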