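# Pretrained word-vector tables in word2vec text format.

#' Load word vectors from word2vec-style text
#'
#' Expects the text format written by fastText/word2vec: an optional header
#' line `"<count> <dim>"`, then one `word v1 ... vD` row per entry. All rows
#' must agree on the dimension; a mismatch (or a dimension different from
#' `expectedDim`) is a load error.
#'
#' @param path file path.
#' @param expectedDim required vector dimension, or `NULL` to accept the
#'   file's dimension.
#' @return list with `dim` (integer) and `vectors` (matrix with one row per
#'   word, words as rownames, lowercased).
#' @export
loadWordVectors <- function(path, expectedDim = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty word-vector file")
  first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  hasHeader <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first)))
  if (hasHeader) lines <- lines[-1L]
  parts <- strsplit(trimws(lines), "[ \t]+")
  dims <- unique(lengths(parts)) - 1L
  if (length(dims) != 1L)
    stop("inconsistent vector dimensions in ", path)
  dim <- dims
  if (hasHeader && dim != as.integer(first[2L]))
    stop(sprintf("header declares dimension %s but rows have %d values",
                 first[2L], dim))
  if (!is.null(expectedDim) && dim != expectedDim)
    stop(sprintf("word vectors have dimension %d, expected %d", dim, expectedDim))
  words <- tolower(vapply(parts, `[[`, character(1), 1L))
  mat <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                nrow = length(parts), ncol = dim, byrow = TRUE)
  keep <- !duplicated(words)
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- words[keep]
  list(dim = dim, vectors = mat)
}

#' Look up the word vector for a token
#'
#' The token text is normalized the way the embedding corpus was preprocessed
#' (lowercased; a digit maps to its English name; symbols normalize to the
#' empty string and so have no entries). Out-of-vocabulary tokens receive the
#' deterministic all-zeros fallback vector — the character pathway of the
#' tagger compensates for missing word vectors.
#'
#' @param tokenText a single token string.
#' @param wordVectors table from [loadWordVectors()], or `NULL`.
#' @param dim vector dimension used for the fallback when `wordVectors` is
#'   `NULL`.
#' @return numeric vector.
#' @export
lookupWordVector <- function(tokenText, wordVectors, dim = if (is.null(wordVectors)) 300L else wordVectors$dim) {
  if (is.null(wordVectors)) return(numeric(dim))
  key <- normalizeForEmbeddings(tokenText)
  if (!nzchar(key)) return(numeric(wordVectors$dim))
  key <- strsplit(key, " ", fixed = TRUE)[[1L]][1L]
  i <- match(key, rownames(wordVectors$vectors))
  if (is.na(i)) return(numeric(wordVectors$dim))
  as.numeric(wordVectors$vectors[i, ])
}
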