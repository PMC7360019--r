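# Shared fixtures: all built in code, nothing read from disk.

# Random strings over a clinical-note-flavored alphabet (letters, digits,
# punctuation, whitespace incl. newlines, a few non-ASCII characters).
randomStrings <- function(n, maxLen = 40L) {
  pool <- c(letters, LETTERS, 0:9, ".", ",", ":", ";", "/", "-", "(", ")",
            "\"", "'", "%", "+", " ", " ", " ", "\n", "\t",
            "é", "µ", "°")
  vapply(seq_len(n), function(i) {
    k <- sample.int(maxLen, 1L)
    paste(sample(pool, k, replace = TRUE), collapse = "")
  }, character(1))
}

# A small reduced configuration used by unit tests (fast, CPU-friendly).
tinyConfig <- function(...) {
  base <- list(wordDim = 6L, charDim = 4L, cnnFilters = 6L, lstmUnits = 5L,
               seqLen = 8L, batchSize = 4L, dropout = 0, recurrentDropout = 0,
               maxEpochs = 3L, seed = 7L)
  over <- list(...)
  base[names(over)] <- over
  do.call(modelConfig, base)
}

# The desk-scale configuration for learning experiments.
deskConfig <- function(seed = 1L, maxEpochs = 15L) {
  modelConfig(wordDim = 50L, charDim = 15L, lstmUnits = 50L,
              maxEpochs = maxEpochs, seed = seed)
}

# A tiny hand-made annotated document.
tinyDoc <- function() {
  text <- "Plan:\nContinue meds.\n120/80 98.6\nDiet: thin liquids\n"
  ann <- data.frame(
    label = c("Sentence", "Sentence", "Unsure", "Sentence", "Sentence"),
    begin = c(0L, 6L, 21L, 33L, 39L),
    end = c(5L, 20L, 32L, 38L, 51L),
    stringsAsFactors = FALSE)
  annotatedDocument("tiny", text, ann)
}

# A linearly separable toy corpus: every line is a short sentence ending
# with a period, so boundaries follow newlines deterministically.
toyCorpus <- function(nDocs = 2L, nLines = 18L, seed = 5L) {
  words <- c("alpha", "beta", "gamma", "delta", "omega")
  set.seed(seed)
  lapply(seq_len(nDocs), function(d) {
    lines <- vapply(seq_len(nLines), function(i) {
      k <- sample(2:4, 1L)
      w <- sample(words, k, replace = TRUE)
      w[1L] <- paste0(toupper(substr(w[1L], 1, 1)), substr(w[1L], 2, nchar(w[1L])))
      paste0(paste(w, collapse = " "), ".")
    }, character(1))
    text <- paste0(paste(lines, collapse = "\n"), "\n")
    starts <- cumsum(c(0L, nchar(lines[-nLines]) + 1L))
    ann <- data.frame(label = "Sentence", begin = starts,
                      end = starts + nchar(lines), stringsAsFactors = FALSE)
    toBioTags(annotatedDocument(sprintf("toy_%d", d), text, ann))
  })
}

# Tagged corpus from the synthetic generator.
synthTagged <- function(profile, nDocs, seed) {
  tagCorpus(generateCorpus(profile, nDocs, seed = seed))
}

# B-tag F1 of a model on a tagged corpus.
bF1 <- function(model, seqs) {
  rep <- evaluateTags(predictTags(model, seqs), lapply(seqs, tags))
  unname(rep@f1["B"])
}
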