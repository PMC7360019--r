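writeTempBrat <- function(text, annLines) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  txt <- file.path(dir, "doc.txt")
  con <- file(txt, "wb"); writeChar(text, con, eos = NULL); close(con)
  ann <- file.path(dir, "doc.ann")
  writeLines(annLines, ann)
  ann
}

test_that("BRAT text-bound annotations parse and validate against the text", {
  ann <- writeTempBrat("Diet: thin liquids\n120 / 80\n",
                       c("T1\tSentence 0 5\tDiet:",
                         "T2\tUnsure 19 27\t120 / 80",
                         "T3\tOtherLabel 0 4\tDiet",
                         "A1\tSomeAttribute T1"))
  expect_warning(doc <- readBrat(ann), "OtherLabel")
  a <- annotations(doc)
  expect_identical(nrow(a), 2L)
  expect_identical(a$label, c("Sentence", "Unsure"))
  expect_identical(a$begin, c(0L, 19L))
  expect_identical(a$end, c(5L, 27L))
  expect_identical(a$text[1], "Diet:")
})

test_that("BRAT integrity and format errors are reported with line numbers", {
  ann <- writeTempBrat("Diet: thin liquids\n", "T1\tSentence 0 5\tWRONG")
  expect_error(readBrat(ann), "line 1.*does not match")
  ann2 <- writeTempBrat("Diet: thin liquids\n", "T1\tSentence 0 5;7 9\tx")
  expect_error(readBrat(ann2), "discontinuous")
  ann3 <- writeTempBrat("Diet\n", "T1\tSentence 0")
  expect_error(readBrat(ann3), "malformed")
  ann4 <- writeTempBrat("Diet\n", "T1\tSentence 0 400\tDiet")
  expect_error(readBrat(ann4), "outside")
})

test_that("writeBrat/readBrat round-trips documents exactly", {
  doc <- tinyDoc()
  dir <- withr::local_tempdir()
  writeBrat(doc, dir)
  back <- readBrat(file.path(dir, "tiny.ann"))
  expect_identical(noteText(back), noteText(doc))
  expect_identical(annotations(back)$begin, annotations(doc)$begin)
  expect_identical(annotations(back)$end, annotations(doc)$end)
  expect_identical(annotations(back)$label, annotations(doc)$label)
})

test_that("span-to-tag conversion applies the B/I/O rule", {
  text <- "Diet: thin liquids"
  doc <- annotatedDocument("d", text, data.frame(
    label = "Sentence", begin = 0L, end = 18L))
  expect_identical(tags(toBioTags(doc)), c("B", "I", "I", "I"))

  uns <- annotatedDocument("u", "120 / 80", data.frame(
    label = "Unsure", begin = 0L, end = 8L))
  expect_identical(tags(toBioTags(uns)), rep("O", 6L))

  two <- annotatedDocument("t", "Plan:\nContinue meds", data.frame(
    label = c("Sentence", "Sentence"), begin = c(0L, 6L), end = c(5L, 19L)))
  expect_identical(tags(toBioTags(two)), c("B", "I", "B", "I"))

  # tokens outside every annotation are O; B count equals span count
  seq <- toBioTags(tinyDoc())
  expect_identical(sum(tags(seq) == "B"), 4L)
})

test_that("Unsure wins over Sentence on overlap, with a message", {
  doc <- new("AnnotatedDocument", docId = "o", text = "abc def",
             annotations = data.frame(
               label = c("Sentence", "Unsure"), begin = c(0L, 4L),
               end = c(7L, 7L), text = c("abc def", "def"),
               stringsAsFactors = FALSE))
  expect_message(seq <- toBioTags(doc), "Unsure wins")
  expect_identical(tags(seq), c("B", "O"))
})

test_that("tag distributions reproduce published count-table arithmetic", {
  mimic <- tagDistribution(c(B = 23648, I = 200272, O = 91877))
  expect_identical(sum(mimic@counts), 315797)
  expect_identical(unname(mimic@percentages[c("B", "I", "O")]),
                   c(7.5, 63.4, 29.1))
  fv <- tagDistribution(c(B = 43636, I = 336018, O = 35458))
  expect_identical(sum(fv@counts), 415112)
  expect_identical(unname(fv@percentages[c("B", "I", "O")]),
                   c(10.5, 80.9, 8.5))
  half <- tagDistribution(c(B = 1, I = 1, O = 0))
  expect_identical(unname(half@percentages[c("B", "I")]), c(50, 50))
  expect_error(tagDistribution(list()), "empty")
})

test_that("termination types classify by final non-whitespace character", {
  counts <- c(period = 12698, exclamation = 4, question = 24, semicolon = 48,
              colon = 4855, quotation = 4, none = 6018)
  ts <- terminationStats(counts)
  expect_identical(unname(ts@percentages["period"]), 53.7)
  expect_identical(unname(ts@percentages["none"]), 25.4)
  expect_identical(unname(ts@percentages["colon"]), 20.5)

  doc <- annotatedDocument("d", "Plan: \n", data.frame(
    label = "Sentence", begin = 0L, end = 6L))  # trailing space stripped
  one <- terminationStats(list(doc))
  expect_identical(unname(one@percentages["colon"]), 100)

  # tinyDoc: "Plan:" and "Diet:" (colon), "Continue meds." (period),
  # "thin liquids" (none)
  docsTs <- terminationStats(list(tinyDoc()))
  expect_identical(unname(docsTs@counts[c("colon", "period", "none")]),
                   c(2, 1, 1))
})

test_that("Cohen's kappa matches a brute-force confusion-matrix oracle", {
  expect_equal(cohensKappa(c("B", "I", "B"), c("B", "I", "B")), 1.0)
  expect_equal(cohensKappa(c("B", "B", "I", "I"), c("B", "I", "B", "I")), 0.0)
  expect_error(cohensKappa(c("B"), c("B", "I")), "equal length")
  expect_warning(k <- cohensKappa(c("B", "B"), c("B", "B")), "undefined")
  expect_true(is.na(k))

  kappaOracle <- function(a, b) {
    labs <- sort(unique(c(a, b)))
    cm <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (i in seq_along(a)) cm[a[i], b[i]] <- cm[a[i], b[i]] + 1
    n <- sum(cm)
    po <- sum(diag(cm)) / n
    pe <- sum(rowSums(cm) * colSums(cm)) / n^2
    (po - pe) / (1 - pe)
  }
  set.seed(21)
  for (r in 1:25) {
    a <- sample(c("B", "I", "O"), 100, replace = TRUE)
    b <- sample(c("B", "I", "O"), 100, replace = TRUE)
    expect_equal(cohensKappa(a, b), kappaOracle(a, b), tolerance = 1e-12)
    keep <- a != "O" & b != "O"
    if (length(unique(c(a[keep], b[keep]))) > 1)
      expect_equal(cohensKappa(a, b, exclude = "O"),
                   kappaOracle(a[keep], b[keep]), tolerance = 1e-12)
  }
})

test_that("corpus splitting is deterministic, disjoint and exhaustive", {
  docs <- as.list(paste0("doc", 1:100))
  sp <- splitCorpus(docs, "cv_only", seed = 1)
  expect_length(sp$train, 80L)
  expect_length(sp$validation, 20L)
  expect_length(sp$test, 0L)
  expect_setequal(unlist(c(sp$train, sp$validation)), unlist(docs))

  sp2 <- splitCorpus(docs, "cv_plus_holdout", seed = 3)
  expect_length(sp2$train, 40L)
  expect_length(sp2$validation, 10L)
  expect_length(sp2$test, 50L)
  expect_setequal(unlist(c(sp2$train, sp2$validation, sp2$test)), unlist(docs))

  expect_identical(splitCorpus(docs, "cv_only", seed = 9),
                   splitCorpus(docs, "cv_only", seed = 9))
  expect_error(splitCorpus(docs[1], "cv_only"), "fewer documents")
})
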