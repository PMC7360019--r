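# Tag-level scoring with O-exclusion, and span reconstruction.

#' Evaluate predicted tags against gold tags
#'
#' Micro-averaged tag-level precision/recall/F1 with O-exclusion: every
#' position whose gold tag is `O` is removed before counting (those regions
#' are un-evaluable, so predictions there are neither right nor wrong). On
#' the remaining two-class positions the scores for `B` and `I` are
#' symmetric: every false-positive `B` is a false-negative `I` and vice
#' versa. `B` scores are the primary metric — they are directly proportional
#' to the accuracy of detected sentence starts.
#'
#' @param predicted list of character vectors (or one vector) over `B`/`I`.
#' @param gold matching gold tags, which may contain `O`.
#' @return an [EvalReport-class].
#' @examples
#' evaluateTags(c("B", "B", "B", "I"), c("B", "I", "O", "I"))
#' @export
evaluateTags <- function(predicted, gold) {
  if (!is.list(predicted)) predicted <- list(predicted)
  if (!is.list(gold)) gold <- list(gold)
  if (length(predicted) != length(gold))
    stop("predicted and gold must have the same number of sequences")
  if (!all(lengths(predicted) == lengths(gold)))
    stop("predicted and gold sequences must have equal lengths")
  p <- unlist(predicted, use.names = FALSE)
  g <- unlist(gold, use.names = FALSE)
  if (any(!p %in% c("B", "I")))
    stop("predicted tags must be B or I (O is never predicted)")
  keep <- g != "O"
  p <- p[keep]; g <- g[keep]
  tp <- c(B = sum(p == "B" & g == "B"), I = sum(p == "I" & g == "I"))
  fp <- c(B = sum(p == "B" & g == "I"), I = sum(p == "I" & g == "B"))
  fn <- c(B = sum(p == "I" & g == "B"), I = sum(p == "B" & g == "I"))
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  new("EvalReport", precision = prec, recall = rec, f1 = f1,
      tp = tp, fp = fp, fn = fn, nEvaluated = length(p))
}

#' Reconstruct sentence spans from B/I tags
#'
#' Each maximal tag run starting at a `B` yields one span from that token's
#' begin offset to the last run token's end offset. A leading `I` run with no
#' preceding `B` forms a span flagged `headless`.
#'
#' @param tokens token table from [tokenizeText()].
#' @param tags character vector over `B`/`I`, one per token.
#' @return `data.frame` with columns `begin`, `end`, `headless`.
#' @export
sentenceSpansFromTags <- function(tokens, tags) {
  stopifnot(nrow(tokens) == length(tags), all(tags %in% c("B", "I")))
  n <- length(tags)
  out <- data.frame(begin = integer(), end = integer(), headless = logical(),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  startIdx <- which(tags == "B")
  headless <- FALSE
  if (length(startIdx) == 0L || startIdx[1L] > 1L) {
    startIdx <- c(1L, startIdx)
    headless <- TRUE
  }
  endIdx <- c(startIdx[-1L] - 1L, n)
  data.frame(begin = tokens$begin[startIdx], end = tokens$end[endIdx],
             headless = c(headless, rep(FALSE, length(startIdx) - 1L)),
             stringsAsFactors = FALSE)
}
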