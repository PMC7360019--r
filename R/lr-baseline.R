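# Logistic-regression character-window baseline.
#
# The baseline scores each token from four 7-character windows (before /
# first / last / after), one-hot encoded over the character vocabulary and
# fed to a sigmoid dense layer — a maximum-entropy-style boundary classifier
# with no recurrence, so every decision rests on 28 characters of local
# evidence. Weights are estimated by penalized maximum likelihood (glmnet);
# prediction runs through the package's own encoding and sigmoid.

.lrDesign <- function(seqs, charVocab, width = 7L) {
  V <- vocabSize(charVocab)
  rows <- list()
  ys <- list()
  masks <- list()
  for (s in seqs) {
    toks <- tokens(s)
    n <- nrow(toks)
    if (n == 0L) next
    ids <- vapply(seq_len(n), function(i)
      vocabIds(charVocab, lrBaselineFeatures(noteText(s), toks, i, width)),
      integer(4L * width))
    rows[[length(rows) + 1L]] <- t(ids)
    ys[[length(ys) + 1L]] <- as.integer(tags(s) == "B")
    masks[[length(masks) + 1L]] <- tags(s) != "O"
  }
  ids <- do.call(rbind, rows)
  n <- nrow(ids)
  k <- 4L * width
  j <- as.vector(t(ids)) + 1L + rep.int((seq_len(k) - 1L) * V, n)
  X <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = j, x = 1,
                            dims = c(n, k * V))
  list(X = X, y = unlist(ys), mask = unlist(masks), V = V, width = width)
}

#' Train the LR character-window baseline
#'
#' Fits the logistic regression on all non-O tokens with the same class
#' weighting as the neural tagger (see [classWeights()]).
#'
#' @param seqs list of [TaggedSequence-class] training sequences.
#' @param charVocab character vocabulary (shared with the neural model for
#'   comparability).
#' @param width window width (default 7).
#' @param lambda ridge-free L1 penalty passed to glmnet (small; the windows
#'   are high-dimensional one-hots).
#' @return baseline parameter list (`w`, `b`, `V`, `width`) consumed by
#'   [lrBaselinePredict()].
#' @export
trainLrBaseline <- function(seqs, charVocab, width = 7L, lambda = 1e-4) {
  d <- .lrDesign(seqs, charVocab, width)
  keep <- d$mask
  X <- d$X[keep, , drop = FALSE]
  y <- d$y[keep]
  cw <- classWeights(c(B = sum(y == 1), I = sum(y == 0)))
  wts <- ifelse(y == 1, cw[["B"]], cw[["I"]])
  # a warm-started path down to the target lambda converges far more
  # reliably than jumping straight to a nearly unpenalized fit
  fit <- glmnet::glmnet(X, y, family = "binomial", weights = wts,
                        lambda = 10^seq(-1, log10(lambda), length.out = 8),
                        standardize = FALSE, maxit = 3e5)
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda))
  list(w = cf[-1L], b = cf[1L], V = d$V, width = d$width)
}

#' Baseline boundary probability
#'
#' `sigmoid(b + sum of the weights at the active one-hot positions)` for one
#' token's window features.
#'
#' @param features symbol vector from [lrBaselineFeatures()] or its 0-based
#'   id encoding.
#' @param params baseline parameters from [trainLrBaseline()] (or any list
#'   with `w`, `b`, `V`).
#' @param charVocab needed when `features` are symbols rather than ids.
#' @return boundary probability.
#' @export
lrBaselinePredict <- function(features, params, charVocab = NULL) {
  ids <- if (is.character(features)) {
    if (is.null(charVocab)) stop("charVocab needed to encode symbol features")
    vocabIds(charVocab, features)
  } else as.integer(features)
  k <- length(ids)
  pos <- ids + 1L + (seq_len(k) - 1L) * params$V
  .sigm(params$b + sum(params$w[pos]))
}

# Batch prediction of B/I tags for whole sequences.
.lrPredictTags <- function(seqs, params, charVocab, threshold = 0.5) {
  lapply(seqs, function(s) {
    toks <- tokens(s)
    n <- nrow(toks)
    if (n == 0L) return(character())
    p <- vapply(seq_len(n), function(i) {
      lrBaselinePredict(
        vocabIds(charVocab,
                 lrBaselineFeatures(noteText(s), toks, i, params$width)),
        params)
    }, numeric(1))
    ifelse(p >= threshold, "B", "I")
  })
}

#' Predict tags with the LR baseline
#'
#' @param seqs list of [TaggedSequence-class] objects.
#' @param params parameters from [trainLrBaseline()].
#' @param charVocab the character vocabulary used in training.
#' @param threshold decision threshold (default 0.5).
#' @return list of character vectors over `B`/`I`.
#' @export
lrBaselineTags <- function(seqs, params, charVocab, threshold = 0.5) {
  .lrPredictTags(seqs, params, charVocab, threshold)
}
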