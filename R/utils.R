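# Internal helpers shared across the package.

# Unicode whitespace class used by the tokenizer (PCRE syntax).
.WS_CLASS <- "\\p{Z}\\t\\n\\x0B\\f\\r\\x{85}"

# A token is a maximal run of letters, or a single non-letter non-whitespace
# character (symbol or digit).
.TOKEN_RE <- paste0("\\p{L}+|[^\\p{L}", .WS_CLASS, "]")

.TAGS <- c("B", "I", "O")

.TERM_TYPES <- c("period", "exclamation", "question", "semicolon", "colon",
                 "quotation", "none")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

.readText <- function(path) {
  raw <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  # normalize Windows/Mac newlines so offsets are stable
  gsub("\r\n?", "\n", raw)
}

.sigm <- function(x) 1 / (1 + exp(-x))

.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
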