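ns <- asNamespace("clinsbd")
SP <- clinsbd:::.SPECIALS

tinyModel <- function(cfg = tinyConfig(), texts = c("Plan: rest.\nAb 12 cd.\n",
                                                    "No pain today.\n")) {
  seqs <- lapply(seq_along(texts), function(i) {
    toks <- tokenizeText(texts[i])
    new("TaggedSequence", docId = paste0("d", i), text = texts[i],
        tokens = toks, tags = rep("I", nrow(toks)))
  })
  cv <- buildCharVocab(seqs)
  wv <- buildWordVocab(seqs)
  list(model = sbdModel(cv, wv, cfg), seqs = seqs)
}

test_that("a zeroed CNN path reduces the word representation to the word vector", {
  tm <- tinyModel()
  m <- tm$model
  m@params$convW[] <- 0
  m@params$convB[] <- 0
  ctx <- charContext(noteText(tm$seqs[[1]]), tokens(tm$seqs[[1]]), 1)
  wvec <- seq_len(m@config$wordDim) / 10
  out <- wordRepresentation(m, wvec, ctx)
  # inference batch norm with fresh statistics (mean 0, var 1, gamma 1, beta 0)
  expect_equal(as.numeric(out), wvec / sqrt(1 + 1e-5), tolerance = 1e-12)
})

test_that("the convolution matches a hand-computed dot product", {
  cfg <- modelConfig(wordDim = 1L, charDim = 2L, cnnFilters = 1L,
                     lstmUnits = 2L, dropout = 0, recurrentDropout = 0,
                     seed = 3L)
  tm <- tinyModel(cfg)
  m <- tm$model
  # hand-set embeddings: symbol with id k embeds to (k, 2k)
  V <- vocabSize(m@charVocab)
  m@params$charEmb <- cbind(0:(V - 1), 2 * (0:(V - 1)))
  m@params$convW <- matrix(c(1, -1, 2, -2, 3, -3, 4, -4), ncol = 1)
  m@params$convB <- 0.5
  syms <- m@charVocab@symbols[3:6]  # four known symbols
  ids <- vocabIds(m@charVocab, syms)
  # one window of width 4: sum_k (w1k*id - w2k*2*id) + b
  w <- m@params$convW[, 1]
  hand <- sum(vapply(1:4, function(k)
    w[2 * k - 1] * ids[k] + w[2 * k] * 2 * ids[k], numeric(1))) + 0.5
  pooled <- max(hand, 0)
  out <- wordRepresentation(m, 0, syms)
  expect_equal(as.numeric(out), pooled / sqrt(1 + 1e-5), tolerance = 1e-10)
})

test_that("contexts differing only beyond the budget give identical representations", {
  tm <- tinyModel()
  m <- tm$model
  text1 <- "aaaa  bbbb"
  text2 <- "zzza  bbbb"
  t1 <- tokenizeText(text1); t2 <- tokenizeText(text2)
  c1 <- charContext(text1, t1, 2); c2 <- charContext(text2, t2, 2)
  expect_identical(c1, c2)
  expect_equal(wordRepresentation(m, numeric(m@config$wordDim), c1),
               wordRepresentation(m, numeric(m@config$wordDim), c2))
})

test_that("the prediction layer is a sigmoid over a dot product", {
  tm <- tinyModel()
  m <- tm$model
  U2 <- 2L * m@config$lstmUnits
  m@params$dense$w <- numeric(U2)
  m@params$dense$b <- 0
  expect_equal(predictBoundaries(m, matrix(rnorm(3 * U2), 3)), rep(0.5, 3))
  m@params$dense$b <- 50
  expect_true(all(predictBoundaries(m, matrix(rnorm(3 * U2), 3)) > 0.999))
  m@params$dense$w <- c(2, -1, rep(0, U2 - 2L))
  m@params$dense$b <- 0.25
  h <- c(0.5, 1.5, rep(0, U2 - 2L))
  expect_equal(predictBoundaries(m, h), 1 / (1 + exp(-(2 * 0.5 - 1.5 + 0.25))))
  expect_error(predictBoundaries(m, matrix(0, 1, 3)), "dimension")
})

test_that("the contextual encoder handles degenerate input and is deterministic", {
  tm <- tinyModel()
  m <- tm$model
  one <- matrix(rnorm(m@config$wordDim), 1)
  out1 <- encodeContext(m, one)
  expect_identical(dim(out1), c(1L, 2L * m@config$lstmUnits))
  X <- matrix(rnorm(5 * m@config$wordDim), 5)
  expect_equal(encodeContext(m, X), encodeContext(m, X))
  expect_identical(nrow(encodeContext(m, X[0, , drop = FALSE])), 0L)
})

test_that("reversing the sequence swaps the role of the two LSTM directions", {
  tm <- tinyModel()
  m <- tm$model
  U <- m@config$lstmUnits
  m2 <- m
  m2@params$fwd <- m@params$bwd
  m2@params$bwd <- m@params$fwd
  X <- matrix(rnorm(6 * m@config$wordDim), 6)
  a <- encodeContext(m, X)
  b <- encodeContext(m2, X[6:1, , drop = FALSE])[6:1, , drop = FALSE]
  # forward states of a == backward states of b and vice versa
  expect_equal(a[, 1:U], b[, (U + 1):(2 * U)], tolerance = 1e-12)
  expect_equal(a[, (U + 1):(2 * U)], b[, 1:U], tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- modelConfig(wordDim = 5L, charDim = 3L, cnnFilters = 5L,
                     lstmUnits = 4L, seqLen = 3L, batchSize = 2L,
                     dropout = 0, recurrentDropout = 0, l1 = 1e-3, seed = 7L)
  docs <- generateCorpus(defaultProfiles()$mimic_like, 2, seed = 3)
  seqs <- lapply(tagCorpus(docs), function(s)
    new("TaggedSequence", docId = docId(s), text = noteText(s),
        tokens = tokens(s)[1:5, ], tags = tags(s)[1:5]))
  cv <- buildCharVocab(seqs)
  model <- sbdModel(cv, buildWordVocab(seqs), cfg)
  enc <- ns$.encodeCorpus(seqs, cv, NULL, cfg)
  bt <- ns$.assembleBatch(ns$.windowsOf(enc, cfg), enc, cfg, c(B = 1.7, I = 0.6))
  params <- model@params
  lossOf <- function(p) ns$.netFwd(p, bt, cfg, train = TRUE)$loss
  fw <- ns$.netFwd(params, bt, cfg, train = TRUE)
  gr <- ns$.netBwd(params, bt, cfg, fw)
  eps <- 1e-6
  set.seed(99)
  for (pth in ns$.trainablePaths(TRUE)) {
    g <- ns$.getPath(gr, pth)
    x <- ns$.getPath(params, pth)
    for (i in sample(length(x), min(5L, length(x)))) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      num <- (lossOf(ns$.setPath(params, pth, xp)) -
                lossOf(ns$.setPath(params, pth, xm))) / (2 * eps)
      if (abs(num) + abs(g[i]) < 1e-7) next  # numerically zero
      expect_lt(abs(num - g[i]) / (abs(num) + abs(g[i])), 1e-4)
    }
  }
})

test_that("parameter count is the closed-form function of the configuration", {
  tm <- tinyModel()
  m <- tm$model
  cfg <- m@config
  V <- vocabSize(m@charVocab)
  D <- cfg$wordDim; dc <- cfg$charDim; U <- cfg$lstmUnits; nf <- cfg$cnnFilters
  expected <- V * dc +                      # char embeddings
    cfg$cnnWidth * dc * nf + nf +           # convolution
    2 * nf +                                # batch norm 1 (gamma, beta)
    2 * (D * 4 * U + U * 4 * U + 4 * U) +   # two LSTM directions
    2 * (2 * U) +                           # batch norm 2
    2 * U + 1                               # prediction layer
  expect_identical(parameterCount(m), as.numeric(expected))
})

test_that("LR baseline windows pad and mark document edges", {
  text <- "ab cde"
  toks <- tokenizeText(text)
  f1 <- lrBaselineFeatures(text, toks, 1)
  expect_length(f1, 28L)
  expect_identical(f1[1:7], c(rep(SP[["PAD"]], 6), SP[["DOC_BEGIN"]]))
  expect_identical(f1[8:14], c("a", "b", rep(SP[["PAD"]], 5)))   # first-7
  expect_identical(f1[15:21], c(rep(SP[["PAD"]], 5), "a", "b"))  # last-7
  expect_identical(f1[22:28], c(" ", "c", "d", "e", SP[["DOC_END"]],
                                rep(SP[["PAD"]], 2)))
  params <- list(w = numeric(28 * 10), b = 0, V = 10L, width = 7L)
  expect_equal(lrBaselinePredict(rep(0L, 28), params), 0.5)
})

test_that("models round-trip through checkpoints with identical predictions", {
  tm <- tinyModel()
  m <- tm$model
  path <- withr::local_tempfile(fileext = ".json")
  saveSbdModel(m, path)
  back <- loadSbdModel(path)
  expect_identical(back@charVocab, m@charVocab)
  expect_equal(back@params, m@params, tolerance = 1e-12)
  p1 <- predictProbs(m, tm$seqs)
  p2 <- predictProbs(back, tm$seqs)
  expect_equal(p1, p2, tolerance = 1e-12)
})
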