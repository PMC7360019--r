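# Synthetic clinical-note generator.
#
# Generates note-like documents with gold Sentence/Unsure spans so the whole
# pipeline — tagging, training, adaptation, evaluation — runs with no access
# to protected health records. Documents mix prose sentences (terminated
# according to a configurable termination-type mix), colon-terminated section
# headers and labels, unterminated list items and fragments, dotted
# abbreviations, numbers, and un-evaluable numeric blocks carrying Unsure
# spans.

.FUNCTION_WORDS <- c("the", "of", "with", "to", "and", "in", "on", "for",
                     "was", "is", "no", "at", "by", "after", "before")

.CAP_NOUNS <- c("Tylenol", "Coumadin", "Lasix", "Heparin", "Zosyn",
                "Protonix", "Ativan", "Morphine", "Colace", "Lipitor",
                "Plavix", "Norvasc", "Keflex", "Augmentin", "Smith",
                "Johnson", "Miller", "Davis")

.ABBREVS <- c("Dr.", "Mr.", "Ms.", "Pt.", "q.d.", "b.i.d.", "t.i.d.",
              "p.o.", "p.r.n.", "h.s.")
.TITLE_ABBREVS <- c("Dr.", "Mr.", "Ms.")

.clinicalLexicon <- function() {
  c("patient", "pain", "chest", "abdominal", "fever", "cough", "lisinopril",
    "metoprolol", "aspirin", "insulin", "glucose", "sodium", "potassium",
    "creatinine", "renal", "cardiac", "pulmonary", "edema", "effusion",
    "fracture", "discharge", "admission", "follow", "clinic", "stable",
    "improved", "denies", "reports", "tolerated", "ambulating", "diet",
    "liquids", "medications", "continue", "monitor", "assess", "wound",
    "incision", "dressing", "afebrile", "alert", "oriented", "bilateral",
    "breath", "sounds", "murmur", "rhythm", "sinus", "tachycardia",
    "hypertension", "diabetes", "mellitus", "copd", "asthma", "pneumonia",
    "sepsis", "infection", "antibiotics", "cultures", "pending", "labs",
    "imaging", "radiograph", "consult", "physical", "therapy",
    "occupational", "speech", "swallow", "nutrition", "supplements",
    "intake", "output", "voiding", "bowel", "regimen", "oral", "daily",
    "nightly", "weekly", "units", "tablet", "capsule", "dose", "titrate",
    "wean", "oxygen", "nasal", "cannula", "room", "air", "saturation",
    "respiratory", "distress", "neuro", "exam", "extremities", "pulses",
    "intact", "skin", "warm", "dry", "mucous", "membranes", "moist",
    "surgical", "history", "family", "social", "smoking", "alcohol",
    "denied", "allergies", "penicillin", "latex", "reaction", "rash",
    "nausea", "vomiting", "diarrhea", "constipation", "appetite", "weight",
    "loss", "gain", "fatigue", "weakness", "dizziness", "headache",
    "vision", "hearing", "plan", "assessment", "impression", "course",
    "hospital", "transfer", "home", "rehab", "services", "orders",
    "telemetry", "overnight", "morning", "evening", "bedside", "nursing",
    "ordered", "reviewed", "discussed", "recommend", "restart", "hold",
    "resume", "taper", "increase", "decrease")
}

.capitalize <- function(w) {
  paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
}

#' Construct a synthetic-domain profile
#'
#' @param name profile name.
#' @param terminationMix named probabilities over the seven termination types
#'   (`period`, `exclamation`, `question`, `semicolon`, `colon`, `quotation`,
#'   `none`), summing to 1.
#' @param unsureRate per-unit probability of emitting an un-evaluable numeric
#'   block (Unsure span) before the unit.
#' @param abbrevRate per-sentence probability of a dotted abbreviation.
#' @param vocabulary word pool for prose.
#' @param formatting list of formatting habits: `wrapWidth` (hard-wrap column,
#'   `Inf` for none), `bulletChar`/`bulletRate` (list-item markers),
#'   `lowercaseStartRate` (fragments starting lowercase),
#'   `pairRate` (next unit continues on the same line after a
#'   symbol-terminated unit), `capitalNounRate` (capitalized drug/name tokens
#'   inside sentences), `headerUpperRate`, `unitsRange`, `proseWords`,
#'   `fragWords`, `numberRate`.
#' @return a [DomainProfile-class].
#' @export
domainProfile <- function(name, terminationMix, unsureRate = 0.05,
                          abbrevRate = 0.2,
                          vocabulary = .clinicalLexicon(),
                          formatting = list()) {
  def <- list(wrapWidth = Inf, bulletChar = "-", bulletRate = 0,
              lowercaseStartRate = 0.05, pairRate = 0.2,
              capitalNounRate = 0.1, headerUpperRate = 0.5,
              unitsRange = c(12L, 22L), proseWords = c(6L, 16L),
              fragWords = c(3L, 7L), numberRate = 0.25)
  def[names(formatting)] <- formatting
  new("DomainProfile", name = name,
      terminationMix = terminationMix[.TERM_TYPES], unsureRate = unsureRate,
      abbrevRate = abbrevRate, vocabulary = vocabulary, formatting = def)
}

#' The two default synthetic domains
#'
#' Two profiles whose sentence termination mixes follow the published
#' distributions for a critical-care corpus (about 25% of sentences carrying
#' no termination symbol, 54% periods, 21% colons) and an RTF-converted
#' outpatient EHR corpus (about 54% unterminated, 31% periods, 14% colons).
#' The source-like domain is hard-wrapped at 55 characters with capitalized
#' drug/name tokens inside sentences, so a line break followed by a capital
#' is genuinely ambiguous between a wrapped continuation and a fragment
#' boundary; the target-like domain is unwrapped but starts most fragments in
#' lowercase and bullets many list items, and its word pool only partially
#' overlaps the source's. Together these produce a measurable domain shift
#' for the adaptation experiments.
#'
#' @param overlap fraction of the lexicon shared between the two domains.
#' @return named list with profiles `mimic_like` and `fv_like`.
#' @export
defaultProfiles <- function(overlap = 0.6) {
  lex <- .clinicalLexicon()
  nShared <- floor(overlap * length(lex))
  nOwn <- floor((length(lex) - nShared) / 2)
  shared <- lex[seq_len(nShared)]
  ownA <- lex[nShared + seq_len(nOwn)]
  ownB <- lex[nShared + nOwn + seq_len(nOwn)]
  mimicMix <- c(period = 12698, exclamation = 4, question = 24,
                semicolon = 48, colon = 4855, quotation = 4, none = 6018)
  fvMix <- c(period = 13619, exclamation = 19, question = 261,
             semicolon = 10, colon = 6180, quotation = 58, none = 23506)
  list(
    mimic_like = domainProfile(
      "mimic_like", mimicMix / sum(mimicMix), unsureRate = 0.08,
      abbrevRate = 0.25, vocabulary = c(shared, ownA),
      formatting = list(wrapWidth = 55, bulletChar = "-", bulletRate = 0.2,
                        lowercaseStartRate = 0.05, pairRate = 0.2,
                        capitalNounRate = 0.12, headerUpperRate = 0.7,
                        unitsRange = c(12L, 22L), proseWords = c(6L, 16L),
                        fragWords = c(3L, 7L), numberRate = 0.25)),
    fv_like = domainProfile(
      "fv_like", fvMix / sum(fvMix), unsureRate = 0.03,
      abbrevRate = 0.15, vocabulary = c(shared, ownB),
      formatting = list(wrapWidth = Inf, bulletChar = "*", bulletRate = 0.4,
                        lowercaseStartRate = 0.7, pairRate = 0.35,
                        capitalNounRate = 0.08, headerUpperRate = 0.1,
                        unitsRange = c(10L, 18L), proseWords = c(5L, 14L),
                        fragWords = c(3L, 8L), numberRate = 0.2)))
}

.sampleWords <- function(k, vocab) {
  fromFn <- stats::runif(k) < 0.35
  w <- character(k)
  if (any(fromFn)) w[fromFn] <- sample(.FUNCTION_WORDS, sum(fromFn), replace = TRUE)
  if (any(!fromFn)) w[!fromFn] <- sample(vocab, sum(!fromFn), replace = TRUE)
  w
}

.rangeSample <- function(r) sample(seq.int(r[1L], r[2L]), 1L)

.randNumber <- function() {
  pick <- stats::runif(1)
  if (pick < 0.3) paste0(sample(90:180, 1L), "/", sample(50:100, 1L))
  else if (pick < 0.6) paste(sample(c(5L, 10L, 20L, 25L, 40L, 50L, 100L), 1L), "mg")
  else as.character(sample(1:400, 1L))
}

.buildProse <- function(prof, terminator) {
  fmt <- prof@formatting
  k <- .rangeSample(fmt$proseWords)
  words <- .sampleWords(k, prof@vocabulary)
  cap <- stats::runif(k) < fmt$capitalNounRate
  if (any(cap)) words[cap] <- sample(.CAP_NOUNS, sum(cap), replace = TRUE)
  if (stats::runif(1) < prof@abbrevRate && k >= 3L) {
    j <- sample(seq_len(k - 2L), 1L)
    ab <- sample(.ABBREVS, 1L)
    ins <- if (ab %in% .TITLE_ABBREVS) c(ab, sample(.CAP_NOUNS, 1L)) else ab
    words <- append(words, ins, after = j)
  }
  if (stats::runif(1) < fmt$numberRate && length(words) >= 2L) {
    j <- sample(seq_len(length(words) - 1L), 1L)
    words <- append(words, .randNumber(), after = j)
  }
  words[1L] <- .capitalize(words[1L])
  body <- paste(words, collapse = " ")
  switch(terminator,
         period = paste0(body, "."),
         exclamation = paste0(body, "!"),
         question = paste0(body, "?"),
         semicolon = paste0(body, ";"),
         quotation = paste0(body, " \"", sample(prof@vocabulary, 1L), "\""),
         paste0(body, "."))
}

.buildHeader <- function(prof) {
  fmt <- prof@formatting
  k <- sample(1:3, 1L)
  words <- sample(prof@vocabulary, k, replace = TRUE)
  words <- if (stats::runif(1) < fmt$headerUpperRate) toupper(words)
  else vapply(words, .capitalize, character(1))
  paste0(paste(words, collapse = " "), ":")
}

.buildFragment <- function(prof) {
  fmt <- prof@formatting
  k <- .rangeSample(fmt$fragWords)
  words <- .sampleWords(k, prof@vocabulary)
  cap <- stats::runif(k) < fmt$capitalNounRate
  if (any(cap)) words[cap] <- sample(.CAP_NOUNS, sum(cap), replace = TRUE)
  if (stats::runif(1) >= fmt$lowercaseStartRate)
    words[1L] <- .capitalize(words[1L])
  body <- paste(words, collapse = " ")
  if (stats::runif(1) < fmt$bulletRate)
    body <- paste0(fmt$bulletChar, " ", body)
  body
}

.buildUnsureBlock <- function() {
  k <- sample(1:3, 1L)
  rows <- vapply(seq_len(k), function(i) {
    m <- sample(3:6, 1L)
    cells <- vapply(seq_len(m), function(j) {
      if (stats::runif(1) < 0.3)
        toupper(paste(sample(letters, sample(2:4, 1L), replace = TRUE),
                      collapse = ""))
      else if (stats::runif(1) < 0.4)
        sprintf("%.1f", sample(10:400, 1L) / 10)
      else as.character(sample(1:400, 1L))
    }, character(1))
    paste(cells, collapse = "  ")
  }, character(1))
  paste(rows, collapse = "\n")
}

# Hard wrap: spaces become newlines past the wrap column, so every character
# offset is preserved. Existing newlines reset the column.
.hardWrap <- function(s, width) {
  if (!is.finite(width)) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  col <- 0L
  lastSp <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "\n") {
      col <- 0L
      lastSp <- 0L
      next
    }
    col <- col + 1L
    if (ch[i] == " ") lastSp <- i
    if (col > width && lastSp > 0L) {
      ch[lastSp] <- "\n"
      col <- i - lastSp
      lastSp <- 0L
    }
  }
  paste(ch, collapse = "")
}

.generateDoc <- function(prof, docId) {
  fmt <- prof@formatting
  nUnits <- .rangeSample(fmt$unitsRange)
  pieces <- character()
  cursor <- 0L
  anns <- list()
  sameLine <- FALSE
  add <- function(unit, label) {
    sep <- if (cursor == 0L) "" else if (sameLine) " " else "\n"
    pieces[[length(pieces) + 1L]] <<- paste0(sep, unit)
    begin <- cursor + nchar(sep)
    anns[[length(anns) + 1L]] <<- data.frame(
      label = label, begin = begin, end = begin + nchar(unit),
      stringsAsFactors = FALSE)
    cursor <<- begin + nchar(unit)
  }
  for (u in seq_len(nUnits)) {
    if (!sameLine && stats::runif(1) < prof@unsureRate) {
      add(.buildUnsureBlock(), "Unsure")
      sameLine <- FALSE
    }
    type <- sample(.TERM_TYPES, 1L, prob = prof@terminationMix)
    unit <- switch(type,
                   colon = .buildHeader(prof),
                   none = .buildFragment(prof),
                   .buildProse(prof, type))
    add(unit, "Sentence")
    sameLine <- type %in% c("period", "colon", "semicolon", "question") &&
      stats::runif(1) < fmt$pairRate
  }
  text <- .hardWrap(paste0(paste(pieces, collapse = ""), "\n"), fmt$wrapWidth)
  ann <- do.call(rbind, anns)
  ann$text <- substring(text, ann$begin + 1L, ann$end)
  annotatedDocument(docId, text, ann)
}

#' Generate a synthetic annotated corpus
#'
#' Seed-deterministic generation of `nDocs` notes under a domain profile.
#' Every sentence-like unit (prose sentence, header, fragment) carries a gold
#' Sentence span whose final non-whitespace character realizes the drawn
#' termination type; every numeric block carries a gold Unsure span.
#'
#' @param profile a [DomainProfile-class].
#' @param nDocs number of documents (>= 1).
#' @param seed integer seed; identical seeds give byte-identical corpora.
#' @return list of [AnnotatedDocument-class] objects.
#' @export
generateCorpus <- function(profile, nDocs, seed = 1L) {
  stopifnot(is(profile, "DomainProfile"), .isCount(nDocs))
  validObject(profile)
  .withSeed(seed, lapply(seq_len(nDocs), function(i) {
    .generateDoc(profile, sprintf("%s_%04d", profile@name, i))
  }))
}
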