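# Corpus construction: positive/negative window extraction, greedy
# identity/coverage clustering, and leakage-controlled splits.

.window_from_annotation <- function(genome, contig, strand, tga_pos, params) {
  s <- .strand_seq(genome[[contig]], strand)
  if (tga_pos < 0L || tga_pos + 3L > nchar(s))
    stop("annotation off contig: ", contig, ":", strand, ":", tga_pos)
  if (.codon_at(s, tga_pos) != "TGA")
    stop("annotated triplet at ", contig, ":", strand, ":", tga_pos,
         " is not TGA")
  .window_strand(s, tga_pos, params)
}

#' Extract positive (Sec-TGA) windows from annotations
#'
#' For each annotated selenoprotein Sec-TGA codon, the window immediately
#' downstream of the TGA is extracted (strand-aware). Exact duplicate
#' sequences are removed.
#'
#' @param annotations Data.frame with columns contig, strand, tga_pos
#'   (0-based strand-local position of the Sec-TGA), family, organism.
#' @param genome Genome as in [enumerateTgaSites()].
#' @param params [ScanParams-class]; `windowLen` sets the window size.
#' @return Data.frame (seq, label = "pos", family, organism).
#' @export
extractPositiveWindows <- function(annotations, genome, params = scanParams()) {
  genome <- .as_genome(genome)
  seqs <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    w <- .window_from_annotation(genome, annotations$contig[i],
                                 annotations$strand[i], annotations$tga_pos[i],
                                 params)
    seqs[i] <- if (is.null(w)) NA_character_ else w$seq
  }
  out <- data.frame(seq = seqs, label = "pos",
                    family = annotations$family,
                    organism = annotations$organism,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$seq), , drop = FALSE]
  out <- out[!duplicated(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract negative (stop-TGA) windows from annotations
#'
#' For annotated genes that genuinely terminate with TGA, extracts the window
#' downstream of the terminal TGA. Source organisms should not use Sec; that
#' is the caller's responsibility and is carried in the organism tag.
#'
#' @param annotations Data.frame with columns contig, strand, tga_pos (0-based
#'   strand-local position of the terminal TGA), organism.
#' @inheritParams extractPositiveWindows
#' @return Data.frame (seq, label = "neg", family = NA, organism).
#' @export
extractNegativeWindows <- function(annotations, genome, params = scanParams()) {
  genome <- .as_genome(genome)
  seqs <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    w <- .window_from_annotation(genome, annotations$contig[i],
                                 annotations$strand[i], annotations$tga_pos[i],
                                 params)
    seqs[i] <- if (is.null(w)) NA_character_ else w$seq
  }
  out <- data.frame(seq = seqs, label = "neg", family = NA_character_,
                    organism = annotations$organism, stringsAsFactors = FALSE)
  out <- out[!is.na(out$seq), , drop = FALSE]
  out <- out[!duplicated(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.cache <- new.env(parent = emptyenv())

.nuc_mat <- function() {
  if (is.null(.cache$nuc))
    .cache$nuc <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  .cache$nuc
}

# Local alignment of one query against many subjects; returns identity
# (matches / aligned columns, gaps included) and per-sequence coverage
# (aligned span / sequence length). Scoring: match +1, mismatch -1, gap
# open 2, gap extend 1.
.align_nt <- function(query, subjects) {
  subj <- Biostrings::DNAStringSet(subjects)
  aln <- Biostrings::pairwiseAlignment(
    pattern = subj, subject = Biostrings::DNAString(query),
    type = "local", substitutionMatrix = .nuc_mat(),
    gapOpening = 2, gapExtension = 1)
  acols <- Biostrings::nchar(aln)
  nm <- Biostrings::nmatch(aln)
  idy <- ifelse(acols > 0, nm / acols, 0)
  pa <- Biostrings::pattern(aln)
  sa <- Biostrings::subject(aln)
  cov_s <- (Biostrings::end(pa) - Biostrings::start(pa) + 1) / nchar(subjects)
  cov_q <- (Biostrings::end(sa) - Biostrings::start(sa) + 1) / nchar(query)
  data.frame(identity = idy, matches = nm, cov_query = cov_q,
             cov_subject = cov_s)
}

#' Pairwise local-alignment identity
#'
#' Identity of the best local alignment between one query and each subject,
#' with the nucleotide scoring used for clustering (match +1, mismatch -1,
#' gap open 2, extend 1). Two normalizations are offered: "columns" (matches
#' over aligned columns, gaps included — the clustering definition, always
#' paired with a coverage requirement) and "shorter" (matches over the
#' shorter sequence length, the CD-HIT convention). Column-normalized local
#' identity alone is degenerate — any short perfect match approaches 100% —
#' so threshold checks without a coverage term should use "shorter".
#'
#' @param query A single nucleotide string.
#' @param subjects Character vector of nucleotide strings.
#' @param normalization "columns" (default) or "shorter".
#' @return Numeric vector of identities in [0, 1].
#' @export
sequenceIdentity <- function(query, subjects,
                             normalization = c("columns", "shorter")) {
  normalization <- match.arg(normalization)
  al <- .align_nt(query, subjects)
  if (normalization == "columns") al$identity
  else al$matches / pmin(nchar(query), nchar(subjects))
}

#' Greedy incremental sequence clustering
#'
#' Sequences are processed by decreasing length (ties broken
#' lexicographically). Each sequence joins the first existing representative
#' with pairwise identity at or above `idThreshold` and bidirectional coverage
#' at or above `covThreshold`; otherwise it founds a new cluster. This is the
#' greedy rule of the CD-HIT/MMseqs family, made reproducible with a built-in
#' aligner.
#'
#' @param seqs Character vector of sequences (at least one).
#' @param idThreshold Identity threshold (default 0.50).
#' @param covThreshold Coverage threshold, required for both sequences
#'   (default 0.80).
#' @return List with `assignment` (cluster index per input sequence) and
#'   `representatives` (input indices of cluster founders, in founding order).
#' @export
greedyCluster <- function(seqs, idThreshold = 0.50, covThreshold = 0.80) {
  if (length(seqs) == 0L) stop("empty input: nothing to cluster")
  ord <- order(-nchar(seqs), seqs)
  assignment <- integer(length(seqs))
  reps <- integer()
  for (i in ord) {
    placed <- FALSE
    if (length(reps)) {
      al <- .align_nt(seqs[i], seqs[reps])
      ok <- which(al$identity >= idThreshold &
                  al$cov_query >= covThreshold &
                  al$cov_subject >= covThreshold)
      if (length(ok)) { assignment[i] <- ok[1L]; placed <- TRUE }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
    }
  }
  list(assignment = assignment, representatives = reps)
}

#' Leakage-controlled train/validation/test splits
#'
#' Implements the family-based protocol: 90% of sequences from
#' `nTrainFamilies` randomly chosen families form the training set; 50% of
#' sequences from `nValFamilies` families chosen from the remainder form the
#' validation set; everything else (unselected sequences of those families
#' plus whole unused families) is a test candidate, kept only if its local
#' identity to every train/val sequence is below `testIdentityCap`. Negatives
#' are randomly partitioned so each split has as many negatives as positives.
#'
#' @param pos Positive windows (data.frame with seq, family, organism).
#' @param neg Negative windows (data.frame with seq).
#' @param nTrainFamilies,trainFrac Training families and per-family fraction
#'   (defaults 40, 0.9).
#' @param nValFamilies,valFrac Validation families and fraction (30, 0.5).
#' @param testIdentityCap Local-identity exclusion threshold for the test set
#'   (default 0.70).
#' @param seed Integer seed.
#' @return List of data.frames `train`, `val`, `test`, each with columns
#'   seq, label, family, organism, split.
#' @export
makeSplits <- function(pos, neg, nTrainFamilies = 40L, trainFrac = 0.9,
                       nValFamilies = 30L, valFrac = 0.5,
                       testIdentityCap = 0.70, seed = 1L) {
  stopifnot(trainFrac > 0, trainFrac <= 1, valFrac > 0, valFrac <= 1,
            testIdentityCap > 0, testIdentityCap < 1)
  pos <- pos[!duplicated(pos$seq), , drop = FALSE]
  neg <- neg[!duplicated(neg$seq), , drop = FALSE]
  fams <- unique(pos$family)
  if (length(fams) < nTrainFamilies + nValFamilies)
    stop("need at least ", nTrainFamilies + nValFamilies, " families, have ",
         length(fams))
  set.seed(seed)
  train_fams <- sample(fams, nTrainFamilies)
  val_fams <- sample(setdiff(fams, train_fams), nValFamilies)

  take <- function(df, frac) {
    n <- nrow(df)
    k <- max(1L, round(frac * n))
    idx <- sample.int(n, k)
    list(inn = df[idx, , drop = FALSE], out = df[-idx, , drop = FALSE])
  }
  tr <- list(); te <- list(); va <- list()
  for (f in train_fams) {
    sp <- take(pos[pos$family == f, , drop = FALSE], trainFrac)
    tr[[f]] <- sp$inn; te[[paste0("t_", f)]] <- sp$out
  }
  for (f in val_fams) {
    sp <- take(pos[pos$family == f, , drop = FALSE], valFrac)
    va[[f]] <- sp$inn; te[[paste0("v_", f)]] <- sp$out
  }
  unused <- setdiff(fams, c(train_fams, val_fams))
  for (f in unused) te[[paste0("u_", f)]] <- pos[pos$family == f, , drop = FALSE]

  train_pos <- do.call(rbind, tr)
  val_pos <- do.call(rbind, va)
  test_pos <- do.call(rbind, te[vapply(te, nrow, 1L) > 0])
  if (is.null(test_pos)) test_pos <- pos[0, , drop = FALSE]

  # identity-based exclusion against train + val (matches normalized by the
  # shorter sequence; see sequenceIdentity)
  ref <- c(train_pos$seq, val_pos$seq)
  if (nrow(test_pos) && length(ref)) {
    keep <- vapply(test_pos$seq, function(q)
      max(sequenceIdentity(q, ref, "shorter")) < testIdentityCap, logical(1))
    test_pos <- test_pos[keep, , drop = FALSE]
  }

  sizes <- c(train = nrow(train_pos), val = nrow(val_pos), test = nrow(test_pos))
  if (sum(sizes) > nrow(neg))
    stop("not enough negative windows to match the positive splits")
  nidx <- sample.int(nrow(neg))
  cuts <- cumsum(sizes)
  neg_train <- neg[nidx[seq_len(cuts[1])], , drop = FALSE]
  neg_val <- neg[nidx[(cuts[1] + 1):cuts[2]], , drop = FALSE]
  neg_test <- if (sizes["test"] > 0)
    neg[nidx[(cuts[2] + 1):cuts[3]], , drop = FALSE] else neg[0, , drop = FALSE]

  finish <- function(p, n, name) {
    n$family <- rep(NA_character_, nrow(n))
    if (is.null(n$organism)) n$organism <- rep(NA_character_, nrow(n))
    n <- n[, c("seq", "label", "family", "organism"), drop = FALSE]
    p <- p[, c("seq", "label", "family", "organism"), drop = FALSE]
    out <- rbind(p, n)
    out$split <- rep(name, nrow(out))
    rownames(out) <- NULL
    out
  }
  list(train = finish(train_pos, neg_train, "train"),
       val = finish(val_pos, neg_val, "val"),
       test = finish(test_pos, neg_test, "test"))
}

#' Write split FASTA files and a manifest TSV
#'
#' @param splits Result of [makeSplits()].
#' @param dir Output directory.
#' @return `dir` invisibly.
#' @export
writeSplitManifest <- function(splits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (nm in names(splits)) {
    df <- splits[[nm]]
    ids <- sprintf("%s_%s_%05d", nm, df$label, seq_len(nrow(df)))
    ss <- Biostrings::DNAStringSet(df$seq)
    names(ss) <- ids
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(nm, ".fasta")))
    manifest[[nm]] <- data.frame(seq_id = ids, label = df$label,
                                 family = df$family, organism = df$organism,
                                 split = rep(nm, nrow(df)))
  }
  write.table(do.call(rbind, manifest), file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
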