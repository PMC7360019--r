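ns <- asNamespace("clinsbd")

test_that("class weights are the equal-distribution ratio over B and I", {
  expect_equal(classWeights(c(B = 50, I = 50)), c(B = 1, I = 1))
  w <- classWeights(c(B = 23648, I = 200272))
  # independent evaluation of w(c) = (1/2) / p(c) on the published counts
  expect_equal(unname(w["B"]), 0.5 * 223920 / 23648, tolerance = 1e-12)
  expect_equal(unname(w["I"]), 0.5 * 223920 / 200272, tolerance = 1e-12)
  expect_equal(unname(round(w, 3)), c(4.734, 0.559))
  expect_gt(w[["B"]], w[["I"]])  # rarer class penalized harder
  expect_error(classWeights(c(B = 0, I = 10)), "positive")
})

test_that("expected class weight under the empirical distribution is one", {
  set.seed(41)
  for (r in 1:50) {
    counts <- c(B = sample(1:10000, 1), I = sample(1:10000, 1))
    w <- classWeights(counts)
    p <- counts / sum(counts)
    expect_equal(sum(p * w), 1, tolerance = 1e-9)
  }
})

test_that("batching cuts documents into masked 32-token windows", {
  profs <- defaultProfiles()
  seqs <- synthTagged(profs$mimic_like, 6, seed = 8)
  # force one document to exactly 70 tokens
  s <- seqs[[1]]
  s70 <- new("TaggedSequence", docId = "s70", text = noteText(s),
             tokens = tokens(s)[1:70, ], tags = tags(s)[1:70])
  cfg <- modelConfig(wordDim = 6, charDim = 4, cnnFilters = 6, lstmUnits = 4,
                     seed = 1)
  model <- sbdModel(buildCharVocab(seqs), buildWordVocab(seqs), cfg)
  enc <- ns$.encodeCorpus(list(s70), model@charVocab, NULL, cfg)
  wnd <- ns$.windowsOf(enc, cfg)
  expect_identical(vapply(wnd, `[[`, integer(1), "len"), c(32L, 32L, 6L))

  bt <- ns$.assembleBatch(wnd, enc, cfg, c(B = 1, I = 1))
  expect_identical(sum(bt$real), 70L)              # padding masked out
  expect_identical(unname(bt$weights[!bt$lossMask]), rep(0, sum(!bt$lossMask)))
  oPos <- which(tags(s70)[1:32] == "O")
  expect_true(all(bt$lossMask[oPos] == FALSE))     # O positions masked

  # 64 windows -> 2 batches of 32
  many <- rep(list(s70), 22)                       # 22 docs x 3 windows = 66
  batches <- makeBatches(many, model, seed = 1)
  expect_identical(unname(vapply(batches, `[[`, integer(1), "B")),
                   c(32L, 32L, 2L))
})

test_that("perturbing padded positions leaves the loss unchanged", {
  profs <- defaultProfiles()
  seqs <- synthTagged(profs$mimic_like, 2, seed = 9)
  # truncate to 20 tokens so the final 8-token window is partly padding
  seqs <- lapply(seqs, function(s)
    new("TaggedSequence", docId = docId(s), text = noteText(s),
        tokens = tokens(s)[1:20, ], tags = tags(s)[1:20]))
  cfg <- tinyConfig()
  model <- sbdModel(buildCharVocab(seqs), buildWordVocab(seqs), cfg)
  enc <- ns$.encodeCorpus(seqs, model@charVocab, NULL, cfg)
  wnd <- ns$.windowsOf(enc, cfg)
  bt <- ns$.assembleBatch(wnd, enc, cfg, c(B = 2, I = 0.5))
  pad <- !bt$real
  expect_gt(sum(pad), 0L)
  l0 <- ns$.netFwd(model@params, bt, cfg, train = TRUE)$loss
  bt2 <- bt
  bt2$Wv[pad, ] <- matrix(rnorm(sum(pad) * cfg$wordDim), sum(pad))
  l1 <- ns$.netFwd(model@params, bt2, cfg, train = TRUE)$loss
  expect_equal(l0, l1, tolerance = 1e-12)
})

test_that("uniformly weighted loss equals plain binary cross-entropy", {
  set.seed(42)
  p <- runif(20, 0.01, 0.99)
  y <- rbinom(20, 1, 0.5)
  w <- rep(1 / 20, 20)
  expect_equal(ns$.weightedBce(p, y, w),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-9)
})

test_that("early stopping keeps the best checkpoint and stops after patience", {
  # strictly decreasing for 3 epochs, then flat for 5 -> stop at 8, keep 3
  r <- ns$.earlyStopEpoch(c(3, 2, 1, 1, 1, 1, 1, 1, 0.5), patience = 5)
  expect_identical(r$stopEpoch, 8L)
  expect_identical(r$bestEpoch, 3L)
  r2 <- ns$.earlyStopEpoch(c(3, 2, 1), patience = 5)
  expect_identical(r2$bestEpoch, 3L)
  # resumed training never returns worse than the incoming checkpoint
  r3 <- ns$.earlyStopEpoch(c(5, 6, 7, 8, 9), patience = 5, initialLoss = 4)
  expect_identical(r3$bestEpoch, 0L)
})

test_that("training is deterministic given the seed", {
  seqs <- toyCorpus(2, 10)
  cfg <- tinyConfig(dropout = 0.3, recurrentDropout = 0.2)
  cfg$maxEpochs <- 1L
  m1 <- sbdModel(buildCharVocab(seqs), buildWordVocab(seqs), cfg)
  f1 <- trainSbdModel(m1, seqs[1], seqs[2])
  f2 <- trainSbdModel(m1, seqs[1], seqs[2])
  expect_identical(f1@trainLog$epochs[[1]]$trainLoss,
                   f2@trainLog$epochs[[1]]$trainLoss)
  expect_identical(f1@trainLog$epochs[[1]]$valLoss,
                   f2@trainLog$epochs[[1]]$valLoss)
})

test_that("training drives the loss down and fits a separable toy corpus", {
  seqs <- toyCorpus(4, 16)
  cfg <- modelConfig(wordDim = 12, charDim = 8, cnnFilters = 12,
                     lstmUnits = 12, dropout = 0, recurrentDropout = 0,
                     batchSize = 4, maxEpochs = 40, seed = 2)
  model <- sbdModel(buildCharVocab(seqs), buildWordVocab(seqs), cfg)
  model <- trainSbdModel(model, seqs[1:3], seqs[4])
  losses <- vapply(model@trainLog$epochs, `[[`, numeric(1), "trainLoss")
  expect_lt(losses[length(losses)], losses[1] / 3)
  pred <- predictTags(model, seqs[1:3])
  rep <- evaluateTags(pred, lapply(seqs[1:3], tags))
  expect_gte(rep@f1[["B"]], 0.99)
})
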