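# Model configuration, construction, and the architecture's exposed
# building blocks.

#' Architecture and training configuration
#'
#' All hyper-parameters of the tagger in one validated list. The published
#' architecture uses 300-dimension word vectors with a 300-filter width-4
#' character CNN over 30-dimension character embeddings, a seven-character
#' context budget per side, sequences of 32 words batched into groups of 32,
#' Adam, and early stopping with patience 5. The LSTM width, dropout rates,
#' L1 strength and learning rate are tuned quantities without published
#' values; the defaults here are conventional settings and are recorded in
#' every training log.
#'
#' @param wordDim word-vector dimension.
#' @param charDim character-embedding dimension.
#' @param cnnFilters number of convolution filters; must equal `wordDim` so
#'   the pooled CNN output can act as an additive adjustment vector.
#' @param cnnWidth convolution width in characters.
#' @param contextChars raw-character budget on each side of a token.
#' @param lstmUnits LSTM units per direction.
#' @param dropout input dropout rate of the LSTM layer (training only).
#' @param recurrentDropout dropout rate on the recurrent connections.
#' @param l1 L1 penalty on the prediction-layer weights.
#' @param seqLen tokens per training window.
#' @param batchSize windows per mini-batch.
#' @param patience epochs without validation-loss improvement before stopping.
#' @param maxEpochs hard epoch cap.
#' @param learningRate Adam step size (Adam moments 0.9/0.999).
#' @param threshold boundary decision threshold on the sigmoid output.
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @return a validated configuration list.
#' @export
modelConfig <- function(wordDim = 300L, charDim = 30L, cnnFilters = wordDim,
                        cnnWidth = 4L, contextChars = 7L, lstmUnits = 200L,
                        dropout = 0.5, recurrentDropout = 0.25, l1 = 1e-5,
                        seqLen = 32L, batchSize = 32L, patience = 5L,
                        maxEpochs = 50L, learningRate = 1e-3,
                        threshold = 0.5, seed = 1L) {
  cfg <- list(wordDim = as.integer(wordDim), charDim = as.integer(charDim),
              cnnFilters = as.integer(cnnFilters),
              cnnWidth = as.integer(cnnWidth),
              contextChars = as.integer(contextChars),
              lstmUnits = as.integer(lstmUnits), dropout = dropout,
              recurrentDropout = recurrentDropout, l1 = l1,
              seqLen = as.integer(seqLen), batchSize = as.integer(batchSize),
              patience = as.integer(patience),
              maxEpochs = as.integer(maxEpochs), learningRate = learningRate,
              threshold = threshold, seed = as.integer(seed))
  if (cfg$wordDim != cfg$cnnFilters)
    stop("cnnFilters must equal wordDim: the pooled CNN output is summed with the word vector")
  if (any(unlist(cfg[c("wordDim", "charDim", "cnnWidth", "contextChars",
                       "lstmUnits", "seqLen", "batchSize")]) < 1L))
    stop("dimensions must be positive")
  if (cfg$dropout < 0 || cfg$dropout >= 1 ||
      cfg$recurrentDropout < 0 || cfg$recurrentDropout >= 1)
    stop("dropout rates must lie in [0, 1)")
  if (cfg$l1 < 0) stop("l1 must be non-negative")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must lie in (0, 1)")
  cfg
}

#' Construct an untrained tagger
#'
#' @param charVocab character vocabulary from [buildCharVocab()].
#' @param wordVocab word vocabulary from [buildWordVocab()].
#' @param config configuration from [modelConfig()].
#' @param wordVectors optional table from [loadWordVectors()] (its dimension
#'   must equal `config$wordDim`); when `NULL`, tokens carry the all-zero
#'   fallback vector and the model relies on the character pathway.
#' @return an [SbdModel-class] with freshly initialized parameters
#'   (deterministic given `config$seed`).
#' @export
sbdModel <- function(charVocab, wordVocab, config = modelConfig(),
                     wordVectors = NULL) {
  stopifnot(is(charVocab, "SymbolVocab"), is(wordVocab, "SymbolVocab"))
  if (!is.null(wordVectors) && wordVectors$dim != config$wordDim)
    stop(sprintf("word vectors have dimension %d but config$wordDim is %d",
                 wordVectors$dim, config$wordDim))
  params <- .initParams(config, vocabSize(charVocab), config$seed)
  new("SbdModel", config = config, charVocab = charVocab,
      wordVocab = wordVocab, wordVectors = wordVectors, params = params,
      trainLog = list())
}

# ---- exposed building blocks -------------------------------------------------

.padCharIds <- function(idsList, cnnWidth) {
  lens <- pmax(lengths(idsList), cnnWidth)
  L <- max(lens)
  C <- matrix(0L, length(idsList), L)
  for (i in seq_along(idsList)) {
    v <- idsList[[i]]
    if (length(v)) C[i, seq_along(v)] <- v
  }
  list(C = C, lens = as.integer(lens))
}

#' Character-enriched word representation
#'
#' Computes `BatchNorm(wordVector + GlobalMaxPool(ReLU(Conv1D(charEmbeddings))))`
#' for one or more tokens at inference (moving batch-norm statistics). The
#' convolution slides a width-`cnnWidth` window over the character-context
#' embeddings; contexts shorter than the width are padded with `<pad>` (id 0,
#' embedding fixed at zero).
#'
#' @param model an [SbdModel-class].
#' @param wordVectors numeric vector (one token) or matrix with one row per
#'   token, dimension `wordDim`.
#' @param charContexts a symbol vector from [charContext()] (one token) or a
#'   list of them.
#' @return matrix with one `wordDim`-column row per token.
#' @export
wordRepresentation <- function(model, wordVectors, charContexts) {
  if (!is.list(charContexts)) charContexts <- list(charContexts)
  if (is.null(dim(wordVectors)))
    wordVectors <- matrix(wordVectors, nrow = 1L)
  stopifnot(nrow(wordVectors) == length(charContexts),
            ncol(wordVectors) == model@config$wordDim)
  ids <- lapply(charContexts, function(s) vocabIds(model@charVocab, s))
  pc <- .padCharIds(ids, model@config$cnnWidth)
  cnn <- .cnnFwd(model@params, pc$C, pc$lens, model@config)
  .bnFwd(wordVectors + cnn$G, model@params$bn1, train = FALSE)$Y
}

#' Contextual encoding of a word-representation sequence
#'
#' Runs the bidirectional LSTM over one sequence of word representations and
#' batch-normalizes the concatenated forward/backward states. Inference mode:
#' dropout off, moving statistics; the result is deterministic.
#'
#' @param model an [SbdModel-class].
#' @param reps matrix, one `wordDim`-column row per token, in order.
#' @return matrix with `2 * lstmUnits` columns, one row per token; a
#'   zero-row input yields a zero-row output.
#' @export
encodeContext <- function(model, reps) {
  cfg <- model@config
  n <- nrow(reps)
  if (n == 0L) return(matrix(0, 0L, 2L * cfg$lstmUnits))
  idxT <- as.list(seq_len(n))
  lf <- .lstmFwd(model@params$fwd, reps, idxT, cfg$lstmUnits, reverse = FALSE)
  lb <- .lstmFwd(model@params$bwd, reps, idxT, cfg$lstmUnits, reverse = TRUE)
  H <- matrix(0, n, 2L * cfg$lstmUnits)
  for (t in seq_len(n)) H[t, ] <- cbind(lf$H[[t]], lb$H[[t]])
  .bnFwd(H, model@params$bn2, train = FALSE)$Y
}

#' Boundary probability from contextual embeddings
#'
#' The sigmoid-activated dense prediction layer, applied per token. The tag
#' decision is `B` when the probability reaches the configured threshold,
#' else `I`.
#'
#' @param model an [SbdModel-class].
#' @param contextual matrix with `2 * lstmUnits` columns.
#' @return numeric vector of boundary probabilities in (0, 1).
#' @export
predictBoundaries <- function(model, contextual) {
  if (is.null(dim(contextual))) contextual <- matrix(contextual, nrow = 1L)
  if (ncol(contextual) != 2L * model@config$lstmUnits)
    stop("contextual embedding dimension mismatch")
  .headFwd(model@params$dense, contextual)
}

# ---- parameter accounting ----------------------------------------------------

.countParams <- function(params, withDense = TRUE) {
  sum(vapply(.trainablePaths(withDense),
             function(p) length(.getPath(params, p)), numeric(1)))
}

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "SbdModel", function(x) .countParams(x@params))

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "SbdEnsembleModel", function(x) {
  .countParams(x@base@params) + .countParams(x@params)
})

# ---- serialization -----------------------------------------------------------

.paramsToPlain <- function(x) {
  if (is.matrix(x)) list(.mat = dim(x), .val = as.numeric(x))
  else if (is.list(x)) lapply(x, .paramsToPlain)
  else x
}

.paramsFromPlain <- function(x) {
  if (is.list(x) && !is.null(x$.mat))
    matrix(as.numeric(unlist(x$.val)), as.integer(x$.mat[[1L]]),
           as.integer(x$.mat[[2L]]))
  else if (is.list(x)) lapply(x, .paramsFromPlain)
  else x
}

.modelToPlain <- function(model) {
  wv <- model@wordVectors
  list(kind = "single", config = model@config,
       charVocab = model@charVocab@symbols,
       wordVocab = model@wordVocab@symbols,
       wordVectors = if (is.null(wv)) NULL else
         list(dim = wv$dim, words = rownames(wv$vectors),
              values = as.numeric(wv$vectors)),
       params = .paramsToPlain(model@params),
       trainLog = model@trainLog)
}

.modelFromPlain <- function(obj) {
  cfg <- do.call(modelConfig, obj$config[names(formals(modelConfig))])
  wv <- NULL
  if (!is.null(obj$wordVectors) && length(obj$wordVectors)) {
    m <- matrix(as.numeric(obj$wordVectors$values),
                nrow = length(obj$wordVectors$words))
    rownames(m) <- obj$wordVectors$words
    wv <- list(dim = as.integer(obj$wordVectors$dim), vectors = m)
  }
  new("SbdModel", config = cfg,
      charVocab = new("SymbolVocab", symbols = as.character(obj$charVocab)),
      wordVocab = new("SymbolVocab", symbols = as.character(obj$wordVocab)),
      wordVectors = wv, params = .paramsFromPlain(obj$params),
      trainLog = if (is.null(obj$trainLog)) list() else obj$trainLog)
}

#' Save / load a model checkpoint
#'
#' A single versioned JSON file embedding the configuration, both
#' vocabularies, the word-vector table if any, and all parameters at full
#' precision. Stacking ensembles are saved with their frozen base embedded.
#'
#' @param model an [SbdModel-class] or [SbdEnsembleModel-class].
#' @param path checkpoint file path.
#' @return `saveSbdModel` returns `path` invisibly; `loadSbdModel` the model.
#' @export
saveSbdModel <- function(model, path) {
  obj <- if (is(model, "SbdEnsembleModel")) {
    list(format = "clinsbd-checkpoint", version = 1L, kind = "ensemble",
         base = .modelToPlain(model@base), config = model@config,
         params = .paramsToPlain(model@params), trainLog = model@trainLog)
  } else {
    c(list(format = "clinsbd-checkpoint", version = 1L),
      .modelToPlain(model))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname saveSbdModel
#' @export
loadSbdModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "clinsbd-checkpoint")
    stop("not a clinsbd checkpoint: ", path)
  if (identical(obj$kind, "ensemble")) {
    cfg <- do.call(modelConfig, obj$config[names(formals(modelConfig))])
    new("SbdEnsembleModel", base = .modelFromPlain(obj$base),
        params = .paramsFromPlain(obj$params), config = cfg,
        trainLog = if (is.null(obj$trainLog)) list() else obj$trainLog)
  } else {
    .modelFromPlain(obj)
  }
}
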