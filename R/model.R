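# Training and scoring of the transformer window classifier. The heavy
# numerics (forward/backward, AdamW) live in src/transformer.cpp; this file
# owns initialization, the masking scheme, epoch scheduling and model
# selection. All randomness flows from ModelConfig@seed through R's RNG so a
# run is reproducible bit-for-bit on one machine.

.param_names <- function(nLayers) {
  per <- c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "ln2_g", "ln2_b", "W1", "b1", "W2", "b2")
  c("tok_emb", "pos_emb",
    unlist(lapply(seq_len(nLayers) - 1L, function(l) paste0("l", l, "_", per))),
    "lnf_g", "lnf_b", "mlm_W", "mlm_b", "cls_W", "cls_b")
}

.init_transformer <- function(cfg, vocab) {
  V <- vocabSize(vocab); d <- cfg@embedDim; TT <- cfg@maxLen
  ff <- cfg@intermediateDim
  wm <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  zc <- function(nr) matrix(0, nr, 1)
  oc <- function(nr) matrix(1, nr, 1)
  p <- list(tok_emb = wm(V, d), pos_emb = wm(TT, d))
  for (l in seq_len(cfg@nLayers)) {
    p <- c(p, list(oc(d), zc(d), wm(d, d), zc(d), wm(d, d), zc(d),
                   wm(d, d), zc(d), wm(d, d), zc(d), oc(d), zc(d),
                   wm(d, ff), zc(ff), wm(ff, d), zc(d)))
  }
  p <- c(p, list(oc(d), zc(d), wm(d, V), zc(V), wm(d, 2), zc(2)))
  names(p) <- .param_names(cfg@nLayers)
  p
}

.zero_like <- function(params) lapply(params, function(m) m * 0)

.draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

# BERT-style masking: 15% of real k-mer tokens per window; of those 80%
# become MASK, 10% a random k-mer id, 10% stay unchanged. Targets carry the
# original id at masked positions and -1 elsewhere.
.mask_tokens <- function(ids, vocab, rate = 0.15) {
  V <- vocabSize(vocab)
  targets <- matrix(-1L, nrow(ids), ncol(ids))
  masked <- ids
  for (i in seq_len(nrow(ids))) {
    cand <- which(ids[i, ] >= 5L)
    if (!length(cand)) next
    nsel <- max(1L, round(rate * length(cand)))
    sel <- if (length(cand) == 1L) cand else sample(cand, nsel)
    targets[i, sel] <- ids[i, sel]
    r <- runif(length(sel))
    masked[i, sel[r < 0.8]] <- .MASK
    rnd <- sel[r >= 0.8 & r < 0.9]
    if (length(rnd)) masked[i, rnd] <- sample(5:(V - 1L), length(rnd), replace = TRUE)
  }
  list(ids = masked, targets = targets)
}

.check_encoded <- function(enc) {
  if (!is.list(enc) || is.null(enc$ids) || is.null(enc$mask))
    stop("expected an encoded-window list from encodeWindows()")
  if (nrow(enc$ids) == 0L) stop("empty corpus")
  invisible(enc)
}

#' Pretrain the encoder with a masked-token objective
#'
#' Runs `pretrainEpochs` epochs of masked-token prediction (15% of k-mer
#' tokens; 80% MASK / 10% random / 10% kept) over unlabeled encoded windows
#' with AdamW. Reproducible given `cfg@seed`.
#'
#' @param enc Encoded windows from [encodeWindows()].
#' @param cfg A [ModelConfig-class].
#' @param vocab The [KmerVocab-class] used for encoding.
#' @param params Optional existing parameter list to continue from.
#' @param verbose Print per-epoch losses.
#' @return A list with `params` (encoder state) and `losses`: the evaluation
#'   loss at initialization followed by the mean training loss of each epoch.
#' @export
pretrainMLM <- function(enc, cfg, vocab, params = NULL, verbose = FALSE) {
  .check_encoded(enc)
  set.seed(cfg@seed)
  if (is.null(params)) params <- .init_transformer(cfg, vocab)
  m <- .zero_like(params); v <- .zero_like(params); step <- 0L
  n <- nrow(enc$ids)

  mk0 <- .mask_tokens(enc$ids, vocab)
  loss0 <- tf_eval_loss(params, mk0$ids, enc$mask, mk0$targets, 0L,
                        cfg@nLayers, cfg@nHeads)
  losses <- loss0
  for (ep in seq_len(cfg@pretrainEpochs)) {
    mk <- .mask_tokens(enc$ids, vocab)
    ord <- sample.int(n)
    fit <- tf_epoch(params, m, v, step, mk$ids, enc$mask, mk$targets, 0L,
                    ord, cfg@pretrainBatch, cfg@learningRate, cfg@weightDecay,
                    cfg@dropout, cfg@nLayers, cfg@nHeads, .draw_seed())
    params <- fit$params; m <- fit$m; v <- fit$v; step <- fit$step
    losses <- c(losses, fit$loss)
    if (verbose) message(sprintf("pretrain epoch %d: loss %.4f", ep, fit$loss))
  }
  list(params = params, losses = losses)
}

.labels_to_int <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("pos", "neg")))
      stop("labels must be 'pos'/'neg' (or logical/0-1)")
    return(as.integer(labels == "pos"))
  }
  as.integer(labels)
}

#' Fine-tune the classification head and encoder
#'
#' Trains for `finetuneEpochs` epochs with cross-entropy and AdamW, logging
#' validation accuracy after each epoch; the returned classifier is the state
#' of the epoch with the highest validation accuracy (earliest epoch on ties).
#'
#' @param state Encoder state from [pretrainMLM()], a raw parameter list, or
#'   `NULL` to train from random initialization.
#' @param trainEnc,trainLabels Encoded training windows and labels
#'   ("pos"/"neg", logical, or 0/1).
#' @param valEnc,valLabels Validation windows and labels.
#' @param cfg A [ModelConfig-class].
#' @param vocab The [KmerVocab-class] used for encoding.
#' @param verbose Print per-epoch progress.
#' @return A [SecClassifier-class].
#' @export
finetuneClassifier <- function(state, trainEnc, trainLabels, valEnc, valLabels,
                               cfg, vocab, verbose = FALSE) {
  .check_encoded(trainEnc); .check_encoded(valEnc)
  ytr <- .labels_to_int(trainLabels)
  yva <- .labels_to_int(valLabels)
  if (length(unique(ytr)) < 2L)
    stop("degenerate labels: training set contains a single class")
  set.seed(cfg@seed + 1L)
  params <- if (is.null(state)) .init_transformer(cfg, vocab)
            else if (!is.null(state$params)) state$params else state
  m <- .zero_like(params); v <- .zero_like(params); step <- 0L
  n <- nrow(trainEnc$ids)
  ytr_m <- matrix(ytr, ncol = 1L)

  hist <- data.frame(epoch = integer(), split = character(),
                     loss = numeric(), accuracy = numeric())
  best_acc <- -Inf; best_params <- params
  for (ep in seq_len(cfg@finetuneEpochs)) {
    ord <- sample.int(n)
    fit <- tf_epoch(params, m, v, step, trainEnc$ids, trainEnc$mask, ytr_m, 1L,
                    ord, cfg@finetuneBatch, cfg@learningRate, cfg@weightDecay,
                    cfg@dropout, cfg@nLayers, cfg@nHeads, .draw_seed())
    params <- fit$params; m <- fit$m; v <- fit$v; step <- fit$step
    pv <- tf_predict(params, valEnc$ids, valEnc$mask, cfg@nLayers, cfg@nHeads)
    acc <- mean((pv[, 2] >= 0.5) == (yva == 1L))
    hist <- rbind(hist,
      data.frame(epoch = ep, split = "train", loss = fit$loss, accuracy = NA_real_),
      data.frame(epoch = ep, split = "val", loss = NA_real_, accuracy = acc))
    if (acc > best_acc) { best_acc <- acc; best_params <- params }
    if (verbose)
      message(sprintf("finetune epoch %d: loss %.4f val acc %.4f", ep, fit$loss, acc))
  }
  new("SecClassifier", params = best_params, config = cfg, vocab = vocab,
      history = hist)
}

#' Train a classifier end to end
#'
#' Convenience wrapper: pretraining on the unlabeled training windows followed
#' by fine-tuning (the pretraining corpus is the training split with labels
#' dropped).
#'
#' @inheritParams finetuneClassifier
#' @param trainSeqs,valSeqs Window character vectors.
#' @return A [SecClassifier-class].
#' @export
trainClassifier <- function(trainSeqs, trainLabels, valSeqs, valLabels,
                            cfg = modelConfig("test"), vocab = buildVocab(cfg@k),
                            verbose = FALSE) {
  tr <- encodeWindows(trainSeqs, vocab, cfg@maxLen)
  va <- encodeWindows(valSeqs, vocab, cfg@maxLen)
  state <- pretrainMLM(tr, cfg, vocab, verbose = verbose)
  finetuneClassifier(state, tr, trainLabels, va, valLabels, cfg, vocab,
                     verbose = verbose)
}

#' Score windows with a trained classifier
#'
#' Returns P(Sec-TGA) per window. Class probabilities sum to one, output
#' order matches input order, and results are independent of batching.
#'
#' @param clf A [SecClassifier-class].
#' @param windows Character vector of windows of the classifier's length, or
#'   an encoded-window list.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
scoreWindows <- function(clf, windows) {
  cfg <- clf@config
  if (is.character(windows)) {
    if (any(nchar(windows) != cfg@windowLen))
      stop("window length does not match the classifier (expected ",
           cfg@windowLen, " nt)")
    windows <- encodeWindows(windows, clf@vocab, cfg@maxLen)
  }
  if (ncol(windows$ids) != cfg@maxLen)
    stop("encoded length does not match the classifier")
  if (nrow(windows$ids) == 0L) return(numeric())
  pv <- tf_predict(clf@params, windows$ids, windows$mask, cfg@nLayers, cfg@nHeads)
  as.numeric(pv[, 2])
}

#' Rank-based AUROC with tie correction
#'
#' Mann-Whitney statistic computed from midranks, equal to the area under the
#' ROC curve with ties counted as half.
#'
#' @param scores Numeric scores.
#' @param labels Positive-class indicator (see [evaluateClassifier()]).
#' @return AUROC in [0, 1].
#' @export
aurocRank <- function(scores, labels) {
  y <- .labels_to_int(labels)
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Classification metrics at a threshold
#'
#' Accuracy, precision, recall, F1 and AUROC from scores and labels using the
#' standard confusion-matrix definitions; AUROC is rank-based with tie
#' correction. Precision is NA when nothing is predicted positive; F1 is 0
#' when precision and recall are both 0.
#'
#' @param scores Numeric vector of P(positive).
#' @param labels "pos"/"neg", logical, or 0/1 labels of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector (accuracy, precision, recall, f1, auroc).
#' @examples
#' evaluateClassifier(c(.9, .8, .2, .6), c("pos", "pos", "neg", "neg"))
#' @export
evaluateClassifier <- function(scores, labels, threshold = 0.5) {
  y <- .labels_to_int(labels)
  if (length(scores) != length(y) || length(y) < 1L)
    stop("scores and labels must be equal-length, non-empty")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  acc <- (tp + tn) / length(y)
  prec <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
    auroc = aurocRank(scores, y))
}

#' Save / load a classifier checkpoint directory
#'
#' A checkpoint is a directory holding the weights, the configuration as
#' JSON, the vocabulary as a token-per-line file, and the training log as TSV.
#'
#' @param clf A [SecClassifier-class].
#' @param dir Checkpoint directory.
#' @return `dir` invisibly (save); a [SecClassifier-class] (load).
#' @export
saveClassifier <- function(clf, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- clf@config
  cfg_list <- sapply(slotNames(cfg), function(s) slot(cfg, s), simplify = FALSE)
  jsonlite::write_json(cfg_list, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeVocab(clf@vocab, file.path(dir, "vocab.txt"))
  saveRDS(clf@params, file.path(dir, "weights.rds"))
  write.table(clf@history, file.path(dir, "training_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(dir) {
  cl <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- modelConfig(cl$profile, windowLen = cl$windowLen, k = cl$k,
                     seed = cl$seed, embedDim = cl$embedDim,
                     nLayers = cl$nLayers, nHeads = cl$nHeads,
                     intermediateDim = cl$intermediateDim, dropout = cl$dropout,
                     pretrainEpochs = cl$pretrainEpochs,
                     pretrainBatch = cl$pretrainBatch,
                     finetuneEpochs = cl$finetuneEpochs,
                     finetuneBatch = cl$finetuneBatch,
                     learningRate = cl$learningRate,
                     weightDecay = cl$weightDecay)
  vocab <- readVocab(file.path(dir, "vocab.txt"))
  hist <- read.delim(file.path(dir, "training_log.tsv"))
  new("SecClassifier", params = readRDS(file.path(dir, "weights.rds")),
      config = cfg, vocab = vocab, history = hist)
}
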