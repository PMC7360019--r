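SP <- clinsbd:::.SPECIALS

test_that("character contexts follow the documented layout", {
  toks <- tokenizeText("Plan")
  expect_identical(charContext("Plan", toks, 1),
                   c(SP[["DOC_BEGIN"]], SP[["WORD_BEGIN"]], "P", "l", "a", "n",
                     SP[["WORD_END"]], SP[["DOC_END"]]))
  t2 <- tokenizeText("A  B")
  expect_identical(charContext("A  B", t2, 2),
                   c(SP[["PREV_END"]], " ", " ", SP[["WORD_BEGIN"]], "B",
                     SP[["WORD_END"]], SP[["DOC_END"]]))
  # newline preserved verbatim in the gap
  t3 <- tokenizeText("a\nb")
  expect_true("\n" %in% charContext("a\nb", t3, 2))
  expect_error(charContext("Plan", toks, 2), "out of range")
})

test_that("long gaps keep the seven characters nearest the token, no marker", {
  text <- paste0("x", strrep(" ", 20), "word")
  toks <- tokenizeText(text)
  ctx <- charContext(text, toks, 2)
  expect_identical(ctx, c(rep(" ", 7), SP[["WORD_BEGIN"]], "w", "o", "r", "d",
                          SP[["WORD_END"]], SP[["DOC_END"]]))
})

test_that("character contexts match a slice-based oracle on random texts", {
  oracle <- function(text, toks, i, k = 7L) {
    n <- nrow(toks); b <- toks$begin[i]; e <- toks$end[i]
    gapL <- substr(text, (if (i == 1) 0L else toks$end[i - 1]) + 1L, b)
    gapR <- substr(text, e + 1L,
                   if (i == n) nchar(text) else toks$begin[i + 1])
    lchars <- strsplit(gapL, "")[[1]]
    rchars <- strsplit(gapR, "")[[1]]
    left <- if (length(lchars) <= k) {
      c(if (i == 1) SP[["DOC_BEGIN"]] else SP[["PREV_END"]], lchars)
    } else utils::tail(lchars, k)
    right <- if (length(rchars) <= k) {
      c(rchars, if (i == n) SP[["DOC_END"]] else SP[["NEXT_BEGIN"]])
    } else utils::head(rchars, k)
    c(left, SP[["WORD_BEGIN"]], strsplit(toks$text[i], "")[[1]],
      SP[["WORD_END"]], right)
  }
  set.seed(31)
  for (s in randomStrings(150, maxLen = 60L)) {
    toks <- tokenizeText(s)
    if (nrow(toks) == 0L) next
    for (i in sample(nrow(toks), min(3L, nrow(toks)))) {
      ctx <- charContext(s, toks, i)
      expect_identical(ctx, unname(oracle(s, toks, i)))
      expect_lte(length(ctx), nchar(toks$text[i]) + 14L + 6L)
    }
  }
})

test_that("contexts are invariant to edits more than 7 characters away", {
  set.seed(32)
  for (r in 1:50) {
    mid <- paste(sample(letters, sample(2:6, 1)), collapse = "")
    text1 <- paste0("onetwothree ", mid, " fourfivesix")
    text2 <- paste0("ONETWOTHR", substr(text1, 10, nchar(text1)))
    text2 <- paste0(substr(text2, 1, nchar(text2) - 3), "SIX")
    t1 <- tokenizeText(text1); t2 <- tokenizeText(text2)
    i <- which(t1$text == mid)
    expect_identical(charContext(text1, t1, i), charContext(text2, t2, i))
  }
})

test_that("vocabularies are deterministic and frequency-ordered with UNK fallback", {
  wv <- buildWordVocab(c("a", "a", "b"))
  expect_lt(vocabIds(wv, "a"), vocabIds(wv, "b"))
  expect_identical(vocabIds(wv, "zz"), vocabIds(wv, "<unk>"))
  expect_identical(buildWordVocab(c("a", "a", "b")), wv)

  docs <- generateCorpus(defaultProfiles()$mimic_like, 3, seed = 2)
  cv1 <- buildCharVocab(docs)
  cv2 <- buildCharVocab(docs)
  expect_identical(cv1, cv2)
  expect_identical(cv1@symbols[1], "<pad>")
  expect_true(all(unname(SP) %in% cv1@symbols))
  expect_error(buildCharVocab(character()), "empty")
})

test_that("vocabularies round-trip through JSON save/load", {
  docs <- generateCorpus(defaultProfiles()$fv_like, 3, seed = 2)
  cv <- buildCharVocab(docs)
  path <- withr::local_tempfile(fileext = ".json")
  saveVocab(cv, path)
  expect_identical(loadVocab(path), cv)
})

test_that("word-vector tables load, validate, and look up with zero fallback", {
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("3 5",
               "diet 0.1 0.2 0.3 0.4 0.5",
               "one -1 -2 -3 -4 -5",
               "plan 1 1 1 1 1"), path)
  wv <- loadWordVectors(path)
  expect_identical(wv$dim, 5L)
  expect_equal(lookupWordVector("Diet", wv), c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(lookupWordVector("1", wv), c(-1, -2, -3, -4, -5))  # digit name
  expect_equal(lookupWordVector(".", wv), numeric(5))             # symbol
  expect_equal(lookupWordVector("unseen", wv), numeric(5))
  expect_error(loadWordVectors(path, expectedDim = 300), "expected 300")
  bad <- withr::local_tempfile()
  writeLines(c("a 1 2", "b 1 2 3"), bad)
  expect_error(loadWordVectors(bad), "inconsistent")
})
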