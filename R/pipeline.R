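# End-to-end orchestration: scan -> window -> score -> homology filter ->
# report, plus GFF3/FASTA/TSV writers.

#' Run the full selenoprotein prediction pipeline
#'
#' Enumerates TGA sites on both strands, reconstructs candidate ORFs,
#' scores the downstream window of each with the classifier, and passes
#' model-positive candidates (score at or above `scoreThreshold`) to the
#' homology filter. Deterministic given the model and inputs.
#'
#' @param genome Genome as in [enumerateTgaSites()].
#' @param classifier A [SecClassifier-class]; its window length and k-mer
#'   size define the scan geometry.
#' @param db Protein database ([Biostrings::AAStringSet] or FASTA path) for
#'   the built-in homology backend.
#' @param hits Optional precomputed hits (data.frame or TSV path) keyed by
#'   candidate id in `qseqid`; used instead of `db` when given.
#' @param params [ScanParams-class]; defaults to the classifier's window
#'   length.
#' @param scoreThreshold Model probability gating the filter stage
#'   (default 0.5).
#' @param maxEvalue,minIdentity Homology thresholds (defaults 0.01, 20).
#' @param knownSet,knownSecPos Curated known-selenoprotein ids and their
#'   annotated Sec positions (see [classifyHit()]).
#' @param seed Integer recorded in the run metadata (the pipeline itself is
#'   deterministic).
#' @return A [PredictionReport-class].
#' @export
runPipeline <- function(genome, classifier, db = NULL, hits = NULL,
                        params = NULL, scoreThreshold = 0.5,
                        maxEvalue = 0.01, minIdentity = 20,
                        knownSet = character(), knownSecPos = NULL,
                        seed = 1L) {
  genome <- .as_genome(genome)
  if (is.null(params)) params <- scanParams(windowLen = windowLength(classifier))
  if (params@windowLen != windowLength(classifier))
    stop("scan window length does not match the classifier")

  scan <- scanGenome(genome, params)
  n_sites <- nrow(scan$sites)
  orfs <- scan$orfs
  n_orfs <- if (is.null(orfs) || nrow(orfs) == 0L) 0L else nrow(orfs)

  cand <- data.frame()
  n_pos <- 0L; n_kept <- 0L
  if (n_orfs > 0L) {
    scores <- scoreWindows(classifier, orfs$window)
    orfs$score <- scores
    sel <- which(scores >= scoreThreshold)
    n_pos <- length(sel)
    rows <- vector("list", n_pos)
    for (j in seq_along(sel)) {
      i <- sel[j]
      orf <- orfs[i, ]
      id <- sprintf("%s_%s_%d", orf$contig, orf$strand, orf$tga_pos)
      prot <- translateOrf(genome, orf)
      hh <- searchHomologs(prot$protein, db = db, hits = hits, qseqid = id,
                           maxEvalue = maxEvalue, minIdentity = minIdentity)
      hh <- classifyHits(hh, prot$sec_index, knownSet, knownSecPos)
      dec <- applyRetentionRule(hh)
      lab <- if (dec$keep) labelKnownOrNew(hh, dec, knownSet)
             else list(status = NA_character_, family = NA_character_)
      rows[[j]] <- data.frame(
        candidate_id = id, contig = orf$contig, strand = orf$strand,
        start_pos = orf$start_pos, tga_pos = orf$tga_pos,
        stop_pos = orf$stop_pos, sec_codon_index = orf$sec_codon_index,
        partial3 = orf$partial3, score = orf$score,
        protein = prot$protein,
        keep = dec$keep, reason = dec$reason,
        label = lab$status, family = lab$family,
        supporting_hits = paste(dec$supporting, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (n_pos > 0L) cand <- do.call(rbind, rows)
    n_kept <- if (n_pos > 0L) sum(cand$keep) else 0L
  }
  new("PredictionReport",
      candidates = cand,
      stageCounts = c(tga_sites = n_sites, valid_orfs = n_orfs,
                      model_positive = n_pos, retained = as.integer(n_kept)),
      metadata = list(score_threshold = scoreThreshold,
                      max_evalue = maxEvalue, min_identity = minIdentity,
                      window_len = params@windowLen,
                      k = kmerSize(classifier), seed = seed))
}

.to_forward_coords <- function(df, contig_lens) {
  L <- contig_lens[df$contig]
  end0 <- ifelse(is.na(df$stop_pos), NA_integer_, df$stop_pos + 3L)
  plus <- df$strand == "+"
  start1 <- ifelse(plus, df$start_pos + 1L, ifelse(is.na(end0), 1L, L - end0 + 1L))
  end1 <- ifelse(plus, ifelse(is.na(end0), L, end0), L - df$start_pos)
  data.frame(start = start1, end = end1)
}

#' Write pipeline outputs
#'
#' Emits, for the retained candidates: a GFF3 file of CDS features (1-based,
#' inclusive, with a `sec_codon_position` attribute giving the 1-based codon
#' index of the Sec TGA), a protein FASTA with 'U' at the Sec position, and
#' a TSV of all model-positive candidates with their decisions. Byte-stable
#' for identical reports.
#'
#' @param report A [PredictionReport-class].
#' @param genome The genome the report was computed from.
#' @param dir Output directory.
#' @return Named character vector of the files written, invisibly.
#' @export
writeOutputs <- function(report, genome, dir) {
  genome <- .as_genome(genome)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cand <- report@candidates
  kept <- if (nrow(cand)) cand[cand$keep, , drop = FALSE] else cand

  gff_path <- file.path(dir, "predictions.gff3")
  faa_path <- file.path(dir, "predictions.faa")
  tsv_path <- file.path(dir, "report.tsv")

  contig_lens <- setNames(Biostrings::width(genome), names(genome))
  if (nrow(kept)) {
    fwd <- .to_forward_coords(kept, contig_lens)
    gr <- GenomicRanges::GRanges(
      seqnames = kept$contig,
      ranges = IRanges::IRanges(start = fwd$start, end = fwd$end),
      strand = kept$strand)
    gr$source <- "selenoscan"
    gr$type <- "CDS"
    gr$score <- round(kept$score, 4)
    gr$phase <- 0L
    gr$ID <- kept$candidate_id
    gr$sec_codon_position <- kept$sec_codon_index + 1L
    gr$label <- kept$label
    rtracklayer::export(gr, gff_path, format = "gff3")
    prot <- Biostrings::AAStringSet(kept$protein)
    names(prot) <- kept$candidate_id
    Biostrings::writeXStringSet(prot, faa_path)
  } else {
    writeLines("##gff-version 3", gff_path)
    file.create(faa_path)
  }
  write.table(cand, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gff3 = gff_path, proteins = faa_path, report = tsv_path))
}
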