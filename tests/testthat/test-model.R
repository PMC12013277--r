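test_that("metrics follow the confusion-matrix definitions", {
  # TP=3 FP=1 FN=1 TN=5
  scores <- c(.9, .8, .7, .3, .6, rep(.1, 5))
  labels <- c(rep("pos", 4), rep("neg", 6))
  m <- evaluateClassifier(scores, labels)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.75)
  expect_equal(unname(m["f1"]), 0.75)
  # perfect separation
  m2 <- evaluateClassifier(c(.9, .8, .1, .2), c("pos", "pos", "neg", "neg"))
  expect_true(all(m2 == 1))
  # F1 is the harmonic mean of precision and recall
  expect_equal(unname(m["f1"]),
               2 * m[["precision"]] * m[["recall"]] /
                 (m[["precision"]] + m[["recall"]]))
  expect_error(evaluateClassifier(c(.1, .2), c("pos", "pos")), "AUROC")
  expect_true(all(m >= 0 & m <= 1))
})

test_that("rank-based AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(40)
  for (i in 1:10) {
    y <- sample(c(0, 1), 60, replace = TRUE, prob = c(.6, .4))
    if (length(unique(y)) < 2) next
    s <- round(runif(60), 1)  # coarse scores force ties
    want <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
      y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))))
    expect_equal(aurocRank(s, y), want, tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(aurocRank(exp(3 * s) - 1, y), aurocRank(s, y))
  }
})

small_mlm_setup <- function(n = 120, L = 100, seed = 41) {
  cfg <- simConfig(motifStrength = 0.8, seed = seed)
  corpus <- simulateCorpus(cfg, n = n / 2, windowLen = L)
  vocab <- buildVocab(3)
  mcfg <- modelConfig("test", windowLen = L, k = 3, seed = seed,
                      nLayers = 1, embedDim = 32, nHeads = 2,
                      intermediateDim = 64, pretrainEpochs = 3,
                      learningRate = 3e-4)
  list(enc = encodeWindows(corpus$seq, vocab, mcfg@maxLen), cfg = mcfg,
       vocab = vocab, corpus = corpus)
}

test_that("masked-token pretraining reduces the loss and is seed-deterministic", {
  s <- small_mlm_setup()
  fit <- pretrainMLM(s$enc, s$cfg, s$vocab)
  expect_lt(fit$losses[length(fit$losses)], fit$losses[1])
  fit2 <- pretrainMLM(s$enc, s$cfg, s$vocab)
  expect_identical(fit$losses, fit2$losses)
  expect_error(pretrainMLM(list(ids = matrix(integer(), 0, 10),
                                mask = matrix(integer(), 0, 10)),
                           s$cfg, s$vocab), "empty")
})

test_that("a corpus of one repeated sequence drives the masked loss near zero", {
  vocab <- buildVocab(3)
  set.seed(42)
  w <- rep(random_dna(100), 60)
  mcfg <- modelConfig("test", windowLen = 100, k = 3, seed = 42,
                      nLayers = 1, embedDim = 32, nHeads = 2,
                      intermediateDim = 64, pretrainEpochs = 40,
                      pretrainBatch = 8, learningRate = 1e-3, dropout = 0)
  enc <- encodeWindows(w, vocab, mcfg@maxLen)
  fit <- pretrainMLM(enc, mcfg, vocab)
  # random-guess loss is log(4^3) ~ 4.16; memorization should approach zero
  expect_lt(fit$losses[length(fit$losses)], 0.5)
})

test_that("fine-tuning selects the epoch with the best validation accuracy", {
  clf <- tiny_classifier()
  hist <- clf@history
  va <- hist[hist$split == "val", ]
  expect_equal(nrow(va), clf@config@finetuneEpochs)
  # rescoring the validation set with the returned state reproduces the max
  cfg <- simConfig(motifStrength = 1, seed = 33L)
  corpus <- simulateCorpus(cfg, n = 150L, windowLen = 100L)
  set.seed(34)
  idx <- sample(nrow(corpus))
  valset <- corpus[idx[241:300], ]
  acc <- mean((scoreWindows(clf, valset$seq) >= 0.5) == (valset$label == "pos"))
  expect_equal(acc, max(va$accuracy))
})

test_that("training rejects degenerate single-class labels", {
  vocab <- buildVocab(3)
  mcfg <- modelConfig("test", windowLen = 100, k = 3, seed = 1,
                      nLayers = 1, embedDim = 32, nHeads = 2,
                      intermediateDim = 64)
  set.seed(43)
  enc <- encodeWindows(vapply(1:8, function(i) random_dna(100), ""), vocab,
                       mcfg@maxLen)
  expect_error(
    finetuneClassifier(NULL, enc, rep("pos", 8), enc, rep("pos", 8),
                       mcfg, vocab),
    "single class")
})

test_that("scores are probabilities, order-preserving and batch invariant", {
  clf <- tiny_classifier()
  set.seed(44)
  seqs <- vapply(1:20, function(i) random_dna(100), "")
  enc <- encodeWindows(seqs, clf@vocab, clf@config@maxLen)
  pv <- selenoscan:::tf_predict(clf@params, enc$ids, enc$mask,
                                clf@config@nLayers, clf@config@nHeads)
  expect_true(all(abs(rowSums(pv) - 1) < 1e-6))
  all_at_once <- scoreWindows(clf, seqs)
  one_by_one <- vapply(seqs, function(s) scoreWindows(clf, s), 0,
                       USE.NAMES = FALSE)
  expect_equal(all_at_once, one_by_one, tolerance = 1e-6)
  # scoring twice is identical
  expect_identical(all_at_once, scoreWindows(clf, seqs))
  expect_error(scoreWindows(clf, random_dna(300)), "length")
})

test_that("a trained model separates planted-motif windows from background", {
  clf <- tiny_classifier()
  cfg <- simConfig(motifStrength = 1, seed = 90L)
  held <- simulateCorpus(cfg, n = 100, windowLen = 100)
  sc <- scoreWindows(clf, held$seq)
  expect_gt(mean(sc[held$label == "pos"]), mean(sc[held$label == "neg"]))
})

test_that("held-out AUROC never degrades as the planted motif strengthens", {
  aucs <- matrix(NA_real_, 3, 3)
  strengths <- c(0.2, 0.5, 0.9)
  for (si in 1:3) for (ri in 1:3) {
    cfg <- simConfig(motifStrength = strengths[si], seed = 50L + ri)
    corpus <- simulateCorpus(cfg, n = 160, windowLen = 100)
    set.seed(60 + ri)
    idx <- sample(nrow(corpus))
    tr <- corpus[idx[1:220], ]; va <- corpus[idx[221:270], ]
    te <- corpus[idx[271:320], ]
    mcfg <- modelConfig("test", windowLen = 100, k = 3, seed = 70L + ri,
                        nLayers = 1, embedDim = 32, nHeads = 2,
                        intermediateDim = 64, pretrainEpochs = 1,
                        finetuneEpochs = 4, learningRate = 3e-4)
    clf <- trainClassifier(tr$seq, tr$label, va$seq, va$label, mcfg)
    aucs[si, ri] <- aurocRank(scoreWindows(clf, te$seq), te$label)
  }
  for (ri in 1:3) {
    expect_gte(aucs[2, ri], aucs[1, ri] - 0.02)
    expect_gte(aucs[3, ri], aucs[2, ri] - 0.02)
  }
})

test_that("the train-and-score path is reproducible under a fixed seed", {
  cfg <- simConfig(motifStrength = 1, seed = 80L)
  corpus <- simulateCorpus(cfg, n = 60, windowLen = 100)
  set.seed(81)
  idx <- sample(nrow(corpus))
  tr <- corpus[idx[1:90], ]; va <- corpus[idx[91:120], ]
  mcfg <- modelConfig("test", windowLen = 100, k = 3, seed = 82L,
                      nLayers = 1, embedDim = 32, nHeads = 2,
                      intermediateDim = 64, pretrainEpochs = 1,
                      finetuneEpochs = 2)
  c1 <- trainClassifier(tr$seq, tr$label, va$seq, va$label, mcfg)
  c2 <- trainClassifier(tr$seq, tr$label, va$seq, va$label, mcfg)
  expect_identical(c1@history, c2@history)
  expect_identical(scoreWindows(c1, va$seq), scoreWindows(c2, va$seq))
})

test_that("classifier checkpoints round-trip through the directory format", {
  clf <- tiny_classifier()
  dir <- withr::local_tempdir()
  saveClassifier(clf, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.rds", "config.json",
                                               "vocab.txt", "training_log.tsv")))))
  clf2 <- loadClassifier(dir)
  set.seed(45)
  seqs <- vapply(1:5, function(i) random_dna(100), "")
  expect_identical(scoreWindows(clf, seqs), scoreWindows(clf2, seqs))
})
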