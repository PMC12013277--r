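#' Scanner parameters
#'
#' Controls TGA-anchored ORF reconstruction and downstream-window extraction.
#' Coordinates throughout the scanner are 0-based, half-open and strand-local:
#' position 0 on the minus strand is the first base of the reverse-complemented
#' contig.
#'
#' @slot windowLen Window length in nt (100, 200 or 300).
#' @slot minUpstreamCodons Minimum number of codons between the start codon
#'   and the candidate TGA (the start codon counts as one of them).
#' @slot minOrfLen Minimum ORF length in nt, start through terminator.
#' @slot terminatorSet Codons treated as terminators downstream of the
#'   candidate TGA. TGA itself is excluded by default because a downstream
#'   in-frame TGA could be a second Sec codon; add it for strict scanning.
#' @slot padShortWindows Pad windows that run off the contig with 'N'.
#' @slot startChoice "farthest" keeps the most upstream in-frame start codon
#'   not separated from the TGA by a terminator (longest-ORF convention);
#'   "nearest" keeps the closest.
#' @export
setClass("ScanParams", representation(
  windowLen = "integer",
  minUpstreamCodons = "integer",
  minOrfLen = "integer",
  terminatorSet = "character",
  padShortWindows = "logical",
  startChoice = "character"
))

setValidity("ScanParams", function(object) {
  msg <- character()
  if (!object@windowLen %in% c(100L, 200L, 300L))
    msg <- c(msg, "windowLen must be one of 100, 200, 300")
  if (object@minOrfLen %% 3L != 0L)
    msg <- c(msg, "minOrfLen must be a multiple of 3")
  if (!all(nchar(object@terminatorSet) == 3L))
    msg <- c(msg, "terminatorSet must contain codons")
  if (!object@startChoice %in% c("farthest", "nearest"))
    msg <- c(msg, "startChoice must be 'farthest' or 'nearest'")
  if (length(msg)) msg else TRUE
})

#' Construct scanner parameters
#'
#' @param windowLen Downstream window length in nt (100, 200 or 300).
#' @param minUpstreamCodons Minimum codons upstream of the TGA (default 10).
#' @param minOrfLen Minimum ORF length in nt (default 90).
#' @param terminatorSet Terminator codons (default TAA and TAG).
#' @param padShortWindows Pad short windows with 'N' (default TRUE).
#' @param startChoice "farthest" (default) or "nearest" upstream start codon.
#' @return A [ScanParams-class] object.
#' @examples
#' scanParams(windowLen = 300)
#' @export
scanParams <- function(windowLen = 300L, minUpstreamCodons = 10L,
                       minOrfLen = 90L, terminatorSet = c("TAA", "TAG"),
                       padShortWindows = TRUE, startChoice = "farthest") {
  new("ScanParams",
      windowLen = as.integer(windowLen),
      minUpstreamCodons = as.integer(minUpstreamCodons),
      minOrfLen = as.integer(minOrfLen),
      terminatorSet = toupper(terminatorSet),
      padShortWindows = padShortWindows,
      startChoice = startChoice)
}

setMethod("show", "ScanParams", function(object) {
  cat("ScanParams: window", object@windowLen, "nt;",
      "min upstream codons", object@minUpstreamCodons, ";",
      "min ORF", object@minOrfLen, "nt;",
      "terminators", paste(object@terminatorSet, collapse = ","), "\n")
})

#' k-mer vocabulary
#'
#' Five special tokens (PAD, UNK, CLS, SEP, MASK at ids 0..4) followed by all
#' 4^k ACGT k-mers in lexicographic order. Ids are dense and 0-based.
#'
#' @slot k k-mer size (3, 4 or 5).
#' @slot tokens Character vector of tokens in id order.
#' @slot index Named integer vector mapping token to 0-based id.
#' @export
setClass("KmerVocab", representation(
  k = "integer", tokens = "character", index = "integer"))

setValidity("KmerVocab", function(object) {
  msg <- character()
  if (!object@k %in% 3:5) msg <- c(msg, "k must be 3, 4 or 5")
  if (length(object@tokens) != 4L^object@k + 5L)
    msg <- c(msg, "vocabulary size must be 4^k + 5")
  if (!identical(object@tokens[1:5], SPECIAL_TOKENS))
    msg <- c(msg, "special tokens must occupy ids 0..4")
  if (length(msg)) msg else TRUE
})

#' @describeIn KmerVocab-class number of tokens in the vocabulary.
#' @param object,x A `KmerVocab`.
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))
setMethod("vocabSize", "KmerVocab", function(x) length(x@tokens))

#' k-mer size accessor
#' @param x An object with a k-mer size (vocabulary or classifier).
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
setMethod("kmerSize", "KmerVocab", function(x) x@k)

setMethod("show", "KmerVocab", function(object) {
  cat("KmerVocab: k =", object@k, "|", length(object@tokens), "tokens\n")
})

#' Transformer model configuration
#'
#' Architecture and training hyperparameters. The "paper" profile is the
#' full-scale configuration (768-dim embeddings, 6 layers, 6 heads, 2048
#' intermediate units, dropout 0.2, masked-token pretraining for 3 epochs at
#' batch 32, fine-tuning for 10 epochs with AdamW at batch 128 and learning
#' rate 1e-6). The "test" profile shrinks the architecture for CPU-scale runs
#' without changing any contract.
#'
#' @slot profile "paper" or "test".
#' @slot embedDim,nLayers,nHeads,intermediateDim Architecture dimensions.
#' @slot dropout Dropout rate applied to hidden layers during training.
#' @slot pretrainEpochs,pretrainBatch Masked-token pretraining schedule.
#' @slot finetuneEpochs,finetuneBatch Fine-tuning schedule.
#' @slot learningRate,weightDecay AdamW hyperparameters.
#' @slot windowLen,k,maxLen Input geometry; maxLen = (windowLen - k + 1) + 2.
#' @slot seed Integer seed controlling initialization, masking, shuffling and
#'   dropout.
#' @export
setClass("ModelConfig", representation(
  profile = "character",
  embedDim = "integer", nLayers = "integer", nHeads = "integer",
  intermediateDim = "integer", dropout = "numeric",
  pretrainEpochs = "integer", pretrainBatch = "integer",
  finetuneEpochs = "integer", finetuneBatch = "integer",
  learningRate = "numeric", weightDecay = "numeric",
  windowLen = "integer", k = "integer", maxLen = "integer",
  seed = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  pos <- c(object@embedDim, object@nLayers, object@nHeads,
           object@intermediateDim, object@pretrainEpochs, object@pretrainBatch,
           object@finetuneEpochs, object@finetuneBatch, object@maxLen)
  if (any(pos <= 0)) msg <- c(msg, "dimensions and schedules must be positive")
  if (object@embedDim %% object@nHeads != 0L)
    msg <- c(msg, "embedDim must be divisible by nHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@maxLen != object@windowLen - object@k + 3L)
    msg <- c(msg, "maxLen must equal (windowLen - k + 1) + 2")
  if (length(msg)) msg else TRUE
})

#' Construct a model configuration
#'
#' @param profile "paper" (full-scale defaults) or "test" (2 layers, 64-dim
#'   embeddings, 4 heads, 256 intermediate units, learning rate 1e-4,
#'   5 fine-tuning epochs at batch 16) for CPU-scale work. The learning rate
#'   is constant, so the smaller fine-tuning batch supplies the optimizer
#'   steps a few-thousand-window corpus needs to converge.
#' @param windowLen Window length the model consumes (default 300).
#' @param k k-mer size (default 3).
#' @param seed Integer seed for all model randomness.
#' @param ... Named overrides for any slot (e.g. `finetuneEpochs = 3`).
#' @return A [ModelConfig-class] object.
#' @examples
#' modelConfig("test", windowLen = 100, k = 3, seed = 7)
#' @export
modelConfig <- function(profile = c("paper", "test"), windowLen = 300L,
                        k = 3L, seed = 1L, ...) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") {
    list(embedDim = 768L, nLayers = 6L, nHeads = 6L, intermediateDim = 2048L,
         dropout = 0.2, pretrainEpochs = 3L, pretrainBatch = 32L,
         finetuneEpochs = 10L, finetuneBatch = 128L, learningRate = 1e-6,
         weightDecay = 0.01)
  } else {
    list(embedDim = 64L, nLayers = 2L, nHeads = 4L, intermediateDim = 256L,
         dropout = 0.2, pretrainEpochs = 2L, pretrainBatch = 32L,
         finetuneEpochs = 5L, finetuneBatch = 16L, learningRate = 1e-4,
         weightDecay = 0.01)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown ModelConfig fields: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  int_fields <- c("embedDim", "nLayers", "nHeads", "intermediateDim",
                  "pretrainEpochs", "pretrainBatch", "finetuneEpochs",
                  "finetuneBatch")
  for (f in int_fields) defaults[[f]] <- as.integer(defaults[[f]])
  new("ModelConfig", profile = profile,
      embedDim = defaults$embedDim, nLayers = defaults$nLayers,
      nHeads = defaults$nHeads, intermediateDim = defaults$intermediateDim,
      dropout = defaults$dropout, pretrainEpochs = defaults$pretrainEpochs,
      pretrainBatch = defaults$pretrainBatch,
      finetuneEpochs = defaults$finetuneEpochs,
      finetuneBatch = defaults$finetuneBatch,
      learningRate = defaults$learningRate, weightDecay = defaults$weightDecay,
      windowLen = as.integer(windowLen), k = as.integer(k),
      maxLen = as.integer(windowLen - k + 3L), seed = as.integer(seed))
}

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig [", object@profile, "]: ", object@nLayers, " layers, ",
      object@embedDim, " dims, ", object@nHeads, " heads, window ",
      object@windowLen, " nt / ", object@k, "-mers\n", sep = "")
})

#' Trained window classifier
#'
#' Holds the trained transformer state, its configuration and vocabulary.
#' Scoring is deterministic: the same batch scored twice yields identical
#' probabilities, independent of batch size.
#'
#' @slot params Ordered list of weight matrices (see `src/transformer.cpp`).
#' @slot config The [ModelConfig-class] used for training.
#' @slot vocab The [KmerVocab-class] the model was trained with.
#' @slot history Per-epoch training log (epoch, split, loss, accuracy).
#' @export
setClass("SecClassifier", representation(
  params = "list", config = "ModelConfig", vocab = "KmerVocab",
  history = "data.frame"))

#' Window length accessor
#' @param x An object with a window length.
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))
setMethod("windowLength", "ScanParams", function(x) x@windowLen)
setMethod("windowLength", "ModelConfig", function(x) x@windowLen)
setMethod("windowLength", "SecClassifier", function(x) x@config@windowLen)
setMethod("kmerSize", "SecClassifier", function(x) x@config@k)
setMethod("kmerSize", "ModelConfig", function(x) x@k)

setMethod("show", "SecClassifier", function(object) {
  best <- if (nrow(object@history)) {
    va <- object@history[object@history$split == "val", "accuracy"]
    if (length(va)) sprintf("; best val accuracy %.3f", max(va)) else ""
  } else ""
  cat("SecClassifier: window ", windowLength(object), " nt / ",
      kmerSize(object), "-mers, ", object@config@nLayers, " layers",
      best, "\n", sep = "")
})

#' Simulation configuration
#'
#' Conditions for the seeded generators: synthetic genomes with planted
#' selenoprotein genes, decoy stop-TGA genes, matched window corpora and
#' fixture homolog databases. The downstream signal is a position weight
#' matrix (PWM) emitted at a fixed offset after the TGA, standing in for the
#' bacterial SECIS element which sits immediately downstream of the Sec codon.
#'
#' @slot genomeLen Genome length in nt.
#' @slot nSelenogenes,nDecoyGenes Number of planted Sec genes and decoys.
#' @slot motifConsensus Consensus of the planted motif (T-free so it cannot
#'   create in-frame stop codons inside genes).
#' @slot motifOffset 0-based offset of the motif within the downstream window.
#' @slot motifStrength Per-position probability mass added to the consensus
#'   base (0 = pure background, 1 = deterministic consensus).
#' @slot gcContent Background GC fraction.
#' @slot seed Integer seed.
#' @export
setClass("SimConfig", representation(
  genomeLen = "integer", nSelenogenes = "integer", nDecoyGenes = "integer",
  motifConsensus = "character", motifOffset = "integer",
  motifStrength = "numeric", gcContent = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@motifStrength < 0 || object@motifStrength > 1)
    msg <- c(msg, "motifStrength must be in [0, 1]")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msg <- c(msg, "gcContent must be in (0, 1)")
  if (grepl("T", object@motifConsensus))
    msg <- c(msg, "motifConsensus must be T-free (no stop codons inside genes)")
  if (object@motifOffset + nchar(object@motifConsensus) > 100L)
    msg <- c(msg, "motif must fit inside the shortest supported window (100 nt)")
  need <- (object@nSelenogenes + object@nDecoyGenes) * 700L
  if (need > object@genomeLen)
    msg <- c(msg, "genomeLen too small for the requested gene counts")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults are the package's reference test scale: a 100-kb genome with 10
#' planted selenoprotein genes and 50 stop-TGA decoys, motif strength 0.8.
#'
#' @param genomeLen Genome length in nt (default 1e5).
#' @param nSelenogenes Planted selenoprotein genes (default 10).
#' @param nDecoyGenes Planted decoy genes ending with stop-TGA (default 50).
#' @param motifConsensus Planted motif consensus (default a T-free 12-mer).
#' @param motifOffset 0-based motif offset within the window (default 10).
#' @param motifStrength Motif strength in [0, 1] (default 0.8).
#' @param gcContent Background GC fraction (default 0.5).
#' @param seed Integer seed (default 1).
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(genomeLen = 100000L, nSelenogenes = 10L,
                      nDecoyGenes = 50L, motifConsensus = "GCCGAGGCAGCC",
                      motifOffset = 10L, motifStrength = 0.8,
                      gcContent = 0.5, seed = 1L) {
  new("SimConfig", genomeLen = as.integer(genomeLen),
      nSelenogenes = as.integer(nSelenogenes),
      nDecoyGenes = as.integer(nDecoyGenes),
      motifConsensus = toupper(motifConsensus),
      motifOffset = as.integer(motifOffset),
      motifStrength = motifStrength, gcContent = gcContent,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@genomeLen, "nt,", object@nSelenogenes,
      "selenogenes,", object@nDecoyGenes, "decoys, motif strength",
      object@motifStrength, "\n")
})

#' Pipeline prediction report
#'
#' Per-candidate results of a full scan/score/filter run, plus stage counts.
#' Stage counts are non-increasing: TGA sites >= valid ORFs >= model-positive
#' >= retained.
#'
#' @slot candidates One row per model-positive candidate: coordinates, score,
#'   decision, reason, known/new label and supporting hit ids.
#' @slot stageCounts Named integer vector (tga_sites, valid_orfs,
#'   model_positive, retained).
#' @slot metadata Run settings (thresholds, seed, model geometry).
#' @export
setClass("PredictionReport", representation(
  candidates = "data.frame", stageCounts = "integer", metadata = "list"))

setValidity("PredictionReport", function(object) {
  sc <- object@stageCounts
  need <- c("tga_sites", "valid_orfs", "model_positive", "retained")
  if (!all(need %in% names(sc))) return("stageCounts incomplete")
  if (any(diff(unname(sc[need])) > 0)) return("stage counts must be non-increasing")
  TRUE
})

#' @describeIn PredictionReport-class candidate table accessor.
#' @param x,object A `PredictionReport`.
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
setMethod("candidates", "PredictionReport", function(x) x@candidates)

#' @describeIn PredictionReport-class stage count accessor.
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))
setMethod("stageCounts", "PredictionReport", function(x) x@stageCounts)

setMethod("show", "PredictionReport", function(object) {
  sc <- object@stageCounts
  cat("PredictionReport: ", sc["tga_sites"], " TGA sites -> ",
      sc["valid_orfs"], " ORFs -> ", sc["model_positive"],
      " model-positive -> ", sc["retained"], " retained\n", sep = "")
})
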