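# BRAT standoff reading and writing.
#
# Only contiguous text-bound ("T") annotations are consumed; fragment
# (discontinuous) spans are rejected, and labels other than Sentence/Unsure
# are skipped with a warning. Offsets in .ann files are 0-based character
# offsets into the paired .txt file.

#' Read a BRAT standoff document
#'
#' Reads a paired `.txt`/`.ann` file into an [AnnotatedDocument-class].
#' Annotation offsets are validated against the text: the covered substring
#' must match the annotation's text field after newline normalization (BRAT
#' writes newlines inside spans as spaces).
#'
#' @param annPath path to the `.ann` standoff file.
#' @param txtPath path to the `.txt` file; defaults to `annPath` with the
#'   extension swapped.
#' @param docId document id; defaults to the file stem.
#' @return an [AnnotatedDocument-class].
#' @export
readBrat <- function(annPath, txtPath = sub("\\.ann$", ".txt", annPath),
                     docId = sub("\\.ann$", "", basename(annPath))) {
  text <- .readText(txtPath)
  lines <- readLines(annPath, warn = FALSE, encoding = "UTF-8")
  anns <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (!startsWith(ln, "T")) next  # relations/events/attributes: not consumed
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop(sprintf("%s line %d: malformed text-bound annotation", annPath, i))
    meta <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
    if (grepl(";", parts[2L], fixed = TRUE))
      stop(sprintf("%s line %d: discontinuous spans are not supported", annPath, i))
    if (length(meta) != 3L)
      stop(sprintf("%s line %d: expected '<label> <begin> <end>'", annPath, i))
    label <- meta[1L]
    if (!label %in% c("Sentence", "Unsure")) {
      warning(sprintf("%s line %d: skipping annotation with label '%s'",
                      annPath, i, label))
      next
    }
    begin <- suppressWarnings(as.integer(meta[2L]))
    end <- suppressWarnings(as.integer(meta[3L]))
    if (is.na(begin) || is.na(end) || end <= begin)
      stop(sprintf("%s line %d: invalid offsets", annPath, i))
    if (begin < 0L || end > nchar(text))
      stop(sprintf("%s line %d: span [%d,%d) outside document of %d characters",
                   annPath, i, begin, end, nchar(text)))
    covered <- substr(text, begin + 1L, end)
    annText <- paste(parts[-(1:2)], collapse = "\t")
    if (gsub("\n", " ", covered, fixed = TRUE) != annText)
      stop(sprintf("%s line %d: annotation text does not match document text ('%s' vs '%s')",
                   annPath, i, annText, covered))
    anns[[length(anns) + 1L]] <-
      data.frame(label = label, begin = begin, end = end, text = covered,
                 stringsAsFactors = FALSE)
  }
  ann <- if (length(anns)) do.call(rbind, anns) else .emptyAnnotations()
  annotatedDocument(docId, text, ann)
}

#' Write a document as a BRAT standoff pair
#'
#' @param doc an [AnnotatedDocument-class].
#' @param dir output directory (created if needed); files are named
#'   `<docId>.txt` and `<docId>.ann`.
#' @return invisibly, the two file paths.
#' @export
writeBrat <- function(doc, dir) {
  stopifnot(is(doc, "AnnotatedDocument"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  txtPath <- file.path(dir, paste0(doc@docId, ".txt"))
  annPath <- file.path(dir, paste0(doc@docId, ".ann"))
  con <- file(txtPath, open = "wb")
  writeChar(doc@text, con, eos = NULL, useBytes = TRUE)
  close(con)
  ann <- doc@annotations
  lines <- character(nrow(ann))
  if (nrow(ann) > 0L) {
    lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(ann)), ann$label,
                     ann$begin, ann$end,
                     gsub("\n", " ", ann$text, fixed = TRUE))
  }
  writeLines(lines, annPath, useBytes = TRUE)
  invisible(c(txt = txtPath, ann = annPath))
}

#' Read a directory of BRAT pairs
#'
#' @param dir directory containing paired `.txt`/`.ann` files.
#' @return list of [AnnotatedDocument-class] objects, ordered by file name.
#' @export
readBratCorpus <- function(dir) {
  anns <- sort(list.files(dir, pattern = "\\.ann$", full.names = TRUE))
  if (!length(anns)) stop("no .ann files in ", dir)
  lapply(anns, readBrat)
}

#' Write a corpus as BRAT pairs
#'
#' @param docs list of [AnnotatedDocument-class] objects.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writeBratCorpus <- function(docs, dir) {
  for (d in docs) writeBrat(d, dir)
  invisible(dir)
}
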