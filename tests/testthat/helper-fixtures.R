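# Shared expensive fixtures, built once per test run. The reference study
# conditions: motif strength 0.8, 2000 + 2000 windows at 300 nt / 3-mers,
# 100-kb genome with 10 planted selenoprotein genes and 50 decoys.

.fixtures <- new.env(parent = emptyenv())

reference_simconfig <- function(seed = 1L) simConfig(seed = seed)

reference_corpus <- function() {
  if (is.null(.fixtures$corpus))
    .fixtures$corpus <- simulateCorpus(reference_simconfig(), n = 2000L,
                                       windowLen = 300L)
  .fixtures$corpus
}

# random 70/15/15 split of the reference corpus
reference_splits <- function() {
  if (is.null(.fixtures$splits)) {
    corpus <- reference_corpus()
    set.seed(101)
    idx <- sample(nrow(corpus))
    n <- length(idx)
    .fixtures$splits <- list(
      train = corpus[idx[1:floor(0.7 * n)], ],
      val = corpus[idx[(floor(0.7 * n) + 1):floor(0.85 * n)], ],
      test = corpus[idx[(floor(0.85 * n) + 1):n], ])
  }
  .fixtures$splits
}

# test-profile classifier trained on the reference corpus (the slow fixture;
# built on first use and shared across test files). The pretrained encoder
# state is kept separately so permutation controls can restart from it.
reference_training <- function() {
  if (is.null(.fixtures$clf)) {
    sp <- reference_splits()
    cfg <- modelConfig("test", windowLen = 300L, k = 3L, seed = 11L)
    vocab <- buildVocab(3L)
    tr_enc <- encodeWindows(sp$train$seq, vocab, cfg@maxLen)
    va_enc <- encodeWindows(sp$val$seq, vocab, cfg@maxLen)
    state <- pretrainMLM(tr_enc, cfg, vocab)
    clf <- finetuneClassifier(state, tr_enc, sp$train$label,
                              va_enc, sp$val$label, cfg, vocab)
    .fixtures$pretrained <- state
    .fixtures$enc <- list(train = tr_enc, val = va_enc)
    .fixtures$clf <- clf
  }
  list(classifier = .fixtures$clf, pretrained = .fixtures$pretrained,
       enc = .fixtures$enc)
}

reference_classifier <- function() reference_training()$classifier

reference_genome <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- reference_simconfig(seed = 2L)
    sim <- simulateGenome(cfg)
    sim$db <- simulateFixtureDb(sim, cfg)
    .fixtures$sim <- sim
  }
  .fixtures$sim
}

# a quick low-capacity classifier for cheap mechanical tests
tiny_classifier <- function() {
  if (is.null(.fixtures$tiny)) {
    cfg <- simConfig(motifStrength = 1, seed = 33L)
    corpus <- simulateCorpus(cfg, n = 150L, windowLen = 100L)
    set.seed(34)
    idx <- sample(nrow(corpus))
    tr <- corpus[idx[1:240], ]; va <- corpus[idx[241:300], ]
    mcfg <- modelConfig("test", windowLen = 100L, k = 3L, seed = 35L,
                        nLayers = 1L, embedDim = 32L, nHeads = 2L,
                        intermediateDim = 64L, pretrainEpochs = 1L,
                        finetuneEpochs = 8L, finetuneBatch = 8L,
                        learningRate = 3e-4)
    .fixtures$tiny <- trainClassifier(tr$seq, tr$label, va$seq, va$label, mcfg)
  }
  .fixtures$tiny
}
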