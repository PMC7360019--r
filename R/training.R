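# Loss weighting, batching geometry, and the optimization loop.

#' Class weights for the B/I loss
#'
#' The binary cross-entropy contribution of each token is weighted by the
#' ratio between an equal distribution over the K = 2 evaluable tags and the
#' empirical tag probability: `w(c) = (1/2) / p(c)`, with `p` computed over
#' non-O tokens. The rarer class (almost always `B`) receives the larger
#' weight, so missing a sentence start is penalized much more than splitting
#' a sentence. The expected weight under the empirical distribution is 1.
#'
#' @param tagCounts named counts with entries `B` and `I` (both positive).
#' @return named numeric weights for `B` and `I`.
#' @examples
#' classWeights(c(B = 50, I = 50))        # both 1
#' classWeights(c(B = 23648, I = 200272)) # B ~ 4.73, I ~ 0.56
#' @export
classWeights <- function(tagCounts) {
  stopifnot(all(c("B", "I") %in% names(tagCounts)))
  counts <- as.numeric(tagCounts[c("B", "I")])
  if (any(counts <= 0)) stop("both B and I counts must be positive")
  p <- counts / sum(counts)
  w <- (1 / 2) / p
  names(w) <- c("B", "I")
  w
}

# ---- encoding ----------------------------------------------------------------

# Precompute everything the network needs for one document: char-context ids,
# word vectors, targets and the loss mask.
.encodeSequence <- function(seq, charVocab, wordVectors, cfg) {
  toks <- tokens(seq)
  n <- nrow(toks)
  ctxs <- .charContextsAll(noteText(seq), toks, cfg$contextChars)
  charIds <- lapply(ctxs, function(s) vocabIds(charVocab, s))
  if (is.null(wordVectors)) {
    wv <- matrix(0, n, cfg$wordDim)
  } else {
    keys <- normalizeForEmbeddings(toks$text)
    keys <- vapply(strsplit(keys, " ", fixed = TRUE),
                   function(p) if (length(p)) p[[1L]] else "", character(1))
    idx <- match(keys, rownames(wordVectors$vectors))
    wv <- matrix(0, n, cfg$wordDim)
    hit <- !is.na(idx) & nzchar(keys)
    if (any(hit)) wv[hit, ] <- wordVectors$vectors[idx[hit], , drop = FALSE]
  }
  tgs <- tags(seq)
  list(charIds = charIds, wv = wv, y = as.integer(tgs == "B"),
       lossMask = tgs != "O", n = n)
}

.encodeCorpus <- function(seqs, charVocab, wordVectors, cfg) {
  lapply(seqs, .encodeSequence, charVocab = charVocab,
         wordVectors = wordVectors, cfg = cfg)
}

# Non-overlapping seqLen-token windows, never crossing a document boundary.
.windowsOf <- function(enc, cfg) {
  out <- list()
  for (d in seq_along(enc)) {
    n <- enc[[d]]$n
    if (n == 0L) next
    starts <- seq.int(1L, n, by = cfg$seqLen)
    for (s in starts) {
      out[[length(out) + 1L]] <- list(doc = d, start = s,
                                      len = min(cfg$seqLen, n - s + 1L))
    }
  }
  out
}

.assembleBatch <- function(windows, enc, cfg, classW) {
  B <- length(windows)
  Tn <- cfg$seqLen
  N <- B * Tn
  charIds <- rep(list(integer()), N)
  Wv <- matrix(0, N, cfg$wordDim)
  y <- numeric(N)
  lossMask <- logical(N)
  real <- logical(N)
  for (b in seq_len(B)) {
    w <- windows[[b]]
    e <- enc[[w$doc]]
    sel <- w$start:(w$start + w$len - 1L)
    rows <- (b - 1L) * Tn + seq_len(w$len)
    charIds[rows] <- e$charIds[sel]
    Wv[rows, ] <- e$wv[sel, , drop = FALSE]
    y[rows] <- e$y[sel]
    lossMask[rows] <- e$lossMask[sel]
    real[rows] <- TRUE
  }
  pc <- .padCharIds(charIds, cfg$cnnWidth)
  nEval <- sum(lossMask)
  weights <- ifelse(y == 1, classW[["B"]], classW[["I"]]) * lossMask
  if (nEval > 0L) weights <- weights / nEval
  idxT <- lapply(seq_len(Tn), function(t) seq.int(t, N, by = Tn))
  list(C = pc$C, lens = pc$lens, Wv = Wv, y = y, lossMask = lossMask,
       real = real, weights = weights, idxT = idxT, B = B, Tn = Tn,
       nEval = nEval)
}

#' Cut a tagged corpus into training batches
#'
#' Documents are cut into consecutive non-overlapping windows of `seqLen`
#' tokens (a final short window is padded, and padding is masked); windows
#' never span documents. Windows are shuffled deterministically under `seed`
#' and grouped into batches of `batchSize`. The loss mask zeroes padded and
#' `O` positions, and per-token weights carry the class weights normalized by
#' the number of unmasked tokens.
#'
#' @param seqs list of [TaggedSequence-class] objects.
#' @param model an [SbdModel-class] supplying vocabularies and configuration.
#' @param seed shuffle seed; `NULL` keeps document order (used for
#'   validation and inference).
#' @return list of batch objects (fields `C`, `lens`, `Wv`, `y`, `lossMask`,
#'   `real`, `weights`, `idxT`, `B`, `Tn`).
#' @export
makeBatches <- function(seqs, model, seed = model@config$seed) {
  if (!length(seqs)) stop("empty corpus")
  cfg <- model@config
  enc <- .encodeCorpus(seqs, model@charVocab, model@wordVectors, cfg)
  counts <- table(factor(unlist(lapply(seqs, tags)), .TAGS))
  classW <- if (counts[["B"]] > 0 && counts[["I"]] > 0)
    classWeights(c(B = counts[["B"]], I = counts[["I"]]))
  else c(B = 1, I = 1)
  wnd <- .windowsOf(enc, cfg)
  if (!is.null(seed)) wnd <- .withSeed(seed, sample(wnd))
  grp <- split(wnd, ceiling(seq_along(wnd) / cfg$batchSize))
  lapply(grp, .assembleBatch, enc = enc, cfg = cfg, classW = classW)
}

# ---- early stopping ----------------------------------------------------------

# Pure early-stopping bookkeeping: given per-epoch validation losses, the
# epoch training stops after and the checkpoint epoch returned ("improvement"
# means strictly lower validation loss; initialLoss guards resumed training).
.earlyStopEpoch <- function(valLosses, patience, initialLoss = Inf) {
  best <- initialLoss
  bestEpoch <- 0L
  since <- 0L
  for (ep in seq_along(valLosses)) {
    if (valLosses[[ep]] < best) {
      best <- valLosses[[ep]]
      bestEpoch <- ep
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) return(list(stopEpoch = ep, bestEpoch = bestEpoch))
  }
  list(stopEpoch = length(valLosses), bestEpoch = bestEpoch)
}

# ---- the fit engine ----------------------------------------------------------

.valLoss <- function(params, valBatches, cfg, baseParams = NULL) {
  tot <- 0
  for (bt in valBatches) {
    fw <- .netFwd(params, bt, cfg, train = FALSE, baseParams = baseParams)
    tot <- tot + .weightedBce(fw$p, bt$y, bt$weights)
  }
  tot / length(valBatches)
}

# Core training loop shared by plain training, continued training, and the
# ensemble (baseParams frozen). All randomness (shuffles, dropout) flows from
# one stream seeded with cfg$seed; the caller's RNG state is untouched.
.fit <- function(params, trainEnc, valBatches, cfg, classW,
                 baseParams = NULL, initialBest = FALSE, verbose = FALSE) {
  paths <- .trainablePaths(withDense = TRUE)
  adam <- .adamInit(params, paths)
  wndAll <- .windowsOf(trainEnc, cfg)
  if (!length(wndAll)) stop("empty training corpus")
  best <- list(loss = if (initialBest)
    .valLoss(params, valBatches, cfg, baseParams) else Inf,
    params = params, epoch = 0L)
  since <- 0L
  log <- list()
  .withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$maxEpochs)) {
      wnd <- sample(wndAll)
      grp <- split(wnd, ceiling(seq_along(wnd) / cfg$batchSize))
      trLoss <- 0
      for (bt in grp) {
        bt <- .assembleBatch(bt, trainEnc, cfg, classW)
        fw <- .netFwd(params, bt, cfg, train = TRUE, baseParams = baseParams)
        if (!is.finite(fw$loss))
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        params <- .applyRunningStats(params, fw$tower$run)
        grads <- .netBwd(params, bt, cfg, fw)
        st <- .adamStep(params, grads, adam, paths, cfg$learningRate)
        params <- st$params
        adam <- st$state
        trLoss <- trLoss + fw$loss
      }
      trLoss <- trLoss / length(grp)
      vaLoss <- .valLoss(params, valBatches, cfg, baseParams)
      log[[epoch]] <- list(epoch = epoch, trainLoss = trLoss,
                           valLoss = vaLoss)
      if (verbose)
        message(sprintf("epoch %d: train %.5f validation %.5f", epoch,
                        trLoss, vaLoss))
      if (vaLoss < best$loss) {
        best <- list(loss = vaLoss, params = params, epoch = epoch)
        since <- 0L
      } else {
        since <- since + 1L
      }
      if (since >= cfg$patience) break
    }
  })
  list(params = best$params,
       log = list(epochs = log, bestEpoch = best$epoch, bestLoss = best$loss,
                  seed = cfg$seed, classWeights = classW,
                  learningRate = cfg$learningRate))
}

.trainClassWeights <- function(seqs) {
  counts <- table(factor(unlist(lapply(seqs, tags)), .TAGS))
  classWeights(c(B = as.numeric(counts[["B"]]), I = as.numeric(counts[["I"]])))
}

#' Train the tagger
#'
#' Optimizes the class-weighted binary cross-entropy (normalized by the
#' number of unmasked tokens, plus the L1 penalty on the prediction layer)
#' with Adam. After every epoch the validation loss is computed at inference;
#' only parameters that improve it are kept, and training stops after
#' `patience` epochs without improvement. The run is deterministic given
#' `config$seed` (single-threaded BLAS assumed).
#'
#' @param model an untrained or pretrained [SbdModel-class].
#' @param train,validation lists of [TaggedSequence-class] objects.
#' @param initialBest when `TRUE`, the incoming parameters' validation loss
#'   is the baseline, so resumed training can never return a worse
#'   checkpoint than it started from (used by [continueTraining()]).
#' @param verbose print per-epoch losses.
#' @return the model with `params` set to the best checkpoint and `trainLog`
#'   holding per-epoch train/validation losses, the best epoch, the seed and
#'   the class weights.
#' @export
trainSbdModel <- function(model, train, validation, initialBest = FALSE,
                          verbose = FALSE) {
  cfg <- model@config
  if (!length(train) || !length(validation)) stop("empty corpus")
  classW <- .trainClassWeights(train)
  trainEnc <- .encodeCorpus(train, model@charVocab, model@wordVectors, cfg)
  valBatches <- makeBatches(validation, model, seed = NULL)
  fit <- .fit(model@params, trainEnc, valBatches, cfg, classW,
              initialBest = initialBest, verbose = verbose)
  model@params <- fit$params
  model@trainLog <- fit$log
  model
}

# ---- inference ---------------------------------------------------------------

.predictEngine <- function(params, baseParams, model, seqs) {
  cfg <- model@config
  enc <- .encodeCorpus(seqs, model@charVocab, model@wordVectors, cfg)
  wnd <- .windowsOf(enc, cfg)
  probs <- lapply(enc, function(e) numeric(e$n))
  grp <- split(wnd, ceiling(seq_along(wnd) / cfg$batchSize))
  for (g in grp) {
    bt <- .assembleBatch(g, enc, cfg, c(B = 1, I = 1))
    fw <- .netFwd(params, bt, cfg, train = FALSE, baseParams = baseParams)
    for (b in seq_along(g)) {
      w <- g[[b]]
      rows <- (b - 1L) * cfg$seqLen + seq_len(w$len)
      probs[[w$doc]][w$start:(w$start + w$len - 1L)] <- fw$p[rows]
    }
  }
  probs
}

#' @rdname predictProbs
#' @export
setMethod("predictProbs", "SbdModel", function(model, seqs, ...) {
  .predictEngine(model@params, NULL, model, seqs)
})

#' @rdname predictProbs
#' @export
setMethod("predictProbs", "SbdEnsembleModel", function(model, seqs, ...) {
  shim <- model@base
  shim@config <- model@config
  .predictEngine(model@params, model@base@params, shim, seqs)
})

.probsToTags <- function(probs, threshold) {
  lapply(probs, function(p) ifelse(p >= threshold, "B", "I"))
}

#' @rdname predictTags
#' @export
setMethod("predictTags", "SbdModel", function(model, seqs, ...) {
  .probsToTags(predictProbs(model, seqs), model@config$threshold)
})

#' @rdname predictTags
#' @export
setMethod("predictTags", "SbdEnsembleModel", function(model, seqs, ...) {
  .probsToTags(predictProbs(model, seqs), model@config$threshold)
})

#' Segment raw text into sentences
#'
#' Tokenizes the text, tags every token with the model, and reconstructs
#' sentence spans from the predicted tag runs.
#'
#' @param model a fitted [SbdModel-class] or [SbdEnsembleModel-class].
#' @param text a document string.
#' @return `data.frame` of sentence spans (`begin`, `end`, `text`,
#'   `headless`); see [sentenceSpansFromTags()].
#' @export
segmentText <- function(model, text) {
  toks <- tokenizeText(text)
  if (nrow(toks) == 0L)
    return(data.frame(begin = integer(), end = integer(), text = character(),
                      headless = logical(), stringsAsFactors = FALSE))
  seq <- new("TaggedSequence", docId = "input", text = enc2utf8(text),
             tokens = toks, tags = rep("I", nrow(toks)))
  tg <- predictTags(model, list(seq))[[1L]]
  spans <- sentenceSpansFromTags(toks, tg)
  spans$text <- substring(text, spans$begin + 1L, spans$end)
  spans
}
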