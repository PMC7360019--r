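#' Tokenize note text
#'
#' Deterministic tokenization used throughout the tagger: the text is split
#' whenever whitespace, a symbol, or a digit is encountered. Each token is
#' either a maximal run of letters or exactly one non-letter, non-whitespace
#' character; whitespace produces no tokens. "Letter" and "whitespace" follow
#' the Unicode categories, so non-ASCII artifacts in EHR text are handled.
#'
#' Offsets are 0-based character offsets with exclusive `end`, so
#' `substr(text, begin + 1, end)` recovers each token and the original text
#' can be reconstructed exactly from the tokens plus the skipped whitespace.
#'
#' @param text a single document string (may be empty).
#' @return `data.frame` with columns `text`, `begin`, `end`, one row per
#'   token, in document order.
#' @examples
#' tokenizeText("1.23")$text              # "1" "." "2" "3"
#' tokenizeText("Diet: thin liquids")$text
#' @export
tokenizeText <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- data.frame(text = character(), begin = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(text) == 0L) return(empty)
  text <- enc2utf8(text)
  m <- gregexpr(.TOKEN_RE, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(text = substring(text, starts, starts + lens - 1L),
             begin = starts - 1L, end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

.DIGIT_NAMES <- c("zero", "one", "two", "three", "four",
                  "five", "six", "seven", "eight", "nine")

#' Normalize text for word-embedding training and lookup
#'
#' Applies the preprocessing under which the word vectors are trained and
#' queried: symbols are replaced with spaces, each digit 0-9 becomes its
#' English name as a separate word (`"1.23"` becomes `"one two three"`), and
#' all letters are lowercased. The result contains only lowercase letters
#' separated by single spaces, and the function is idempotent.
#'
#' @param text character vector.
#' @return normalized character vector of the same length.
#' @examples
#' normalizeForEmbeddings("1.23")      # "one two three"
#' normalizeForEmbeddings("BP 120/80") # "bp one two zero eight zero"
#' @export
normalizeForEmbeddings <- function(text) {
  text <- enc2utf8(as.character(text))
  for (d in 0:9) {
    text <- gsub(as.character(d), paste0(" ", .DIGIT_NAMES[d + 1L], " "),
                 text, fixed = TRUE)
  }
  text <- gsub("[^\\p{L}]", " ", text, perl = TRUE)
  text <- tolower(text)
  text <- gsub(" {2,}", " ", text)
  trimws(text)
}
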