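# Homology-based validation of candidate selenoprotein ORFs: translation
# with U at the Sec codon, hit gathering (built-in local-alignment backend or
# precomputed tabular hits), classification of the residue aligned to the Sec
# position, and the retention rule: keep a candidate if it has at least one
# known Sec-containing homolog, or at least two of its top ten hits are
# Cys-containing homologs from different organisms.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "evalue", "bitscore",
                 "qstart", "qend", "sstart", "send", "qseq_aln", "sseq_aln",
                 "organism")

.genetic_code_11 <- function() {
  if (is.null(.cache$gc11))
    .cache$gc11 <- Biostrings::getGeneticCode("11")
  .cache$gc11
}

#' Translate a candidate ORF with U at the Sec codon
#'
#' Bacterial translation table 11. The initial codon (ATG, CTG or GTG)
#' becomes 'M', the candidate TGA becomes 'U' (selenocysteine), codons with
#' ambiguous bases become 'X', and the terminator is excluded. An in-frame
#' TAA/TAG before the terminator violates the ORF contract and is an error.
#'
#' @param genome Genome as in [enumerateTgaSites()].
#' @param orf One-row data.frame from [findCandidateOrf()] (or a list with
#'   the same fields).
#' @return List with `protein` (amino-acid string containing one 'U') and
#'   `sec_index` (1-based position of the U).
#' @export
translateOrf <- function(genome, orf) {
  genome <- .as_genome(genome)
  s <- .strand_seq(genome[[orf$contig]], orf$strand)
  n <- nchar(s)
  end_nt <- if (!is.na(orf$stop_pos)) orf$stop_pos else
    orf$start_pos + ((n - orf$start_pos) %/% 3L) * 3L
  nt <- substr(s, orf$start_pos + 1L, end_nt)
  codons <- substring(nt, seq(1L, nchar(nt) - 2L, by = 3L),
                      seq(3L, nchar(nt), by = 3L))
  code <- .genetic_code_11()
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  sec_i <- orf$sec_codon_index + 1L
  if (any(codons %in% c("TAA", "TAG")))
    stop("in-frame terminator inside ORF: contract violation")
  # a second in-frame TGA is scanned as its own candidate; here it reads as X
  aa[codons == "TGA"] <- "X"
  aa[1L] <- "M"
  aa[sec_i] <- "U"
  list(protein = paste(aa, collapse = ""), sec_index = sec_i)
}

# BLOSUM62 has no selenocysteine row; score with U replaced by C (or X) and
# restore original residues into the aligned strings afterwards.
.restore_aligned <- function(aln_str, original, start) {
  ch <- strsplit(aln_str, "")[[1]]
  nongap <- which(ch != "-")
  ch[nongap] <- strsplit(substr(original, start, start + length(nongap) - 1L),
                         "")[[1]]
  paste(ch, collapse = "")
}

.parse_organism <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
}

.parse_family <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, "")
}

# Ungapped Karlin-Altschul constants for BLOSUM62; the resulting e-value is
# deterministic but not calibrated against any production aligner.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Search a protein database for homologs of a candidate
#'
#' Built-in backend: Smith-Waterman local alignment (BLOSUM62, gap open 11,
#' extend 1) of the candidate (Sec sent as Cys, or 'X' via
#' `secSubstitution`) against every database sequence, with a deterministic
#' pseudo e-value from the ungapped Karlin-Altschul formula — useful for
#' fixtures and tests, not calibrated like a production aligner.
#' Alternatively, precomputed tabular hits (see [readHitsTable()]) can be
#' supplied. Hits are filtered at `maxEvalue` and `minIdentity` and sorted by
#' (evalue, -bitscore, sseqid).
#'
#' @param protein Candidate protein string with 'U' at the Sec position.
#' @param db An [Biostrings::AAStringSet] (names in "id|organism|family"
#'   form) or FASTA path; ignored when `hits` is given.
#' @param hits Optional precomputed hit data.frame/TSV path with the columns
#'   in `HIT_COLUMNS`.
#' @param qseqid Query id recorded in the hit table.
#' @param maxEvalue E-value cutoff (default 0.01).
#' @param minIdentity Percent-identity cutoff (default 20).
#' @param secSubstitution Residue substituted for U when scoring ("C",
#'   default, maximizes Cys-homolog detectability; or "X").
#' @return Data.frame of hits with `HIT_COLUMNS`.
#' @export
searchHomologs <- function(protein, db = NULL, hits = NULL, qseqid = "query",
                           maxEvalue = 0.01, minIdentity = 20,
                           secSubstitution = c("C", "X")) {
  secSubstitution <- match.arg(secSubstitution)
  if (!is.null(hits)) {
    if (is.character(hits)) hits <- readHitsTable(hits)
    out <- hits[hits$qseqid == qseqid | length(unique(hits$qseqid)) == 1L, ,
                drop = FALSE]
  } else {
    if (is.null(db)) stop("backend unavailable: provide a database or hits")
    if (is.character(db) && length(db) == 1L && file.exists(db))
      db <- Biostrings::readAAStringSet(db)
    if (length(db) == 0L) return(.empty_hits())
    qc <- gsub("U", secSubstitution, protein, fixed = TRUE)
    subj_chr <- as.character(db)
    subj_c <- gsub("U", "C", subj_chr, fixed = TRUE)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(subj_c),
      subject = Biostrings::AAString(qc),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    score <- Biostrings::score(aln)
    bit <- (.KA_LAMBDA * score - log(.KA_K)) / log(2)
    evalue <- nchar(protein) * sum(nchar(subj_chr)) * 2^(-bit)
    acols <- Biostrings::nchar(aln)
    pident <- ifelse(acols > 0, 100 * Biostrings::nmatch(aln) / acols, 0)
    pa <- Biostrings::pattern(aln); sa <- Biostrings::subject(aln)
    sstart <- Biostrings::start(pa); send <- Biostrings::end(pa)
    qstart <- Biostrings::start(sa); qend <- Biostrings::end(sa)
    n <- length(db)
    qa_str <- sa_str <- character(n)
    for (i in seq_len(n)) {
      qa_str[i] <- .restore_aligned(as.character(sa[i]), protein, qstart[i])
      sa_str[i] <- .restore_aligned(as.character(pa[i]), subj_chr[i], sstart[i])
    }
    out <- data.frame(qseqid = qseqid, sseqid = names(db), pident = pident,
                      evalue = evalue, bitscore = bit, qstart = qstart,
                      qend = qend, sstart = sstart, send = send,
                      qseq_aln = qa_str, sseq_aln = sa_str,
                      organism = .parse_organism(names(db)),
                      stringsAsFactors = FALSE)
  }
  out <- out[out$evalue <= maxEvalue & out$pident >= minIdentity, , drop = FALSE]
  out <- out[order(out$evalue, -out$bitscore, out$sseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  out <- data.frame(qseqid = character(), sseqid = character(),
                    pident = numeric(), evalue = numeric(),
                    bitscore = numeric(), qstart = integer(),
                    qend = integer(), sstart = integer(), send = integer(),
                    qseq_aln = character(), sseq_aln = character(),
                    organism = character(), stringsAsFactors = FALSE)
  out
}

#' Read / write the tabular hits dialect
#'
#' Tab-separated with a header line and the 12 columns qseqid, sseqid,
#' pident, evalue, bitscore, qstart, qend, sstart, send, qseq_aln, sseq_aln,
#' organism (the familiar tabular-alignment columns plus the two aligned
#' strings and an organism tag).
#'
#' @param path File path.
#' @param hits Hit data.frame.
#' @return Data.frame of hits (read); `path` invisibly (write).
#' @export
readHitsTable <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(HIT_COLUMNS, names(out))
  if (length(missing))
    stop("hits table lacks columns: ", paste(missing, collapse = ", "))
  out
}

#' @rdname readHitsTable
#' @export
writeHitsTable <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify the residue a hit aligns to the candidate's Sec position
#'
#' Walks the aligned strings of one hit and inspects the subject residue in
#' the column where the query's Sec sits: 'U' (or a curated known
#' selenoprotein whose annotated Sec lands there) is a Sec-containing
#' homolog, 'C' a Cys-containing homolog, and anything else — another
#' residue, a gap, or a Sec position outside the aligned span — is "other".
#'
#' @param hit One-row data.frame (or list) with the hit columns.
#' @param secQueryPos 1-based Sec position in the query protein.
#' @param knownSet Character vector of subject ids curated as known
#'   selenoproteins.
#' @param knownSecPos Optional named integer vector: annotated Sec position
#'   (1-based) per known subject id.
#' @return One of "sec_homolog", "cys_homolog", "other".
#' @export
classifyHit <- function(hit, secQueryPos, knownSet = character(),
                        knownSecPos = NULL) {
  if (secQueryPos < hit$qstart || secQueryPos > hit$qend) return("other")
  qa <- strsplit(hit$qseq_aln, "")[[1]]
  sa <- strsplit(hit$sseq_aln, "")[[1]]
  qpos <- hit$qstart - 1L
  spos <- hit$sstart - 1L
  for (i in seq_along(qa)) {
    if (qa[i] != "-") qpos <- qpos + 1L
    if (sa[i] != "-") spos <- spos + 1L
    if (qa[i] != "-" && qpos == secQueryPos) {
      if (sa[i] == "-") return("other")
      if (sa[i] == "U") return("sec_homolog")
      if (hit$sseqid %in% knownSet && !is.null(knownSecPos) &&
          !is.na(knownSecPos[hit$sseqid]) && spos == knownSecPos[hit$sseqid])
        return("sec_homolog")
      if (sa[i] == "C") return("cys_homolog")
      return("other")
    }
  }
  "other"
}

#' Classify all hits of a candidate
#'
#' @param hits Hit data.frame from [searchHomologs()].
#' @inheritParams classifyHit
#' @return `hits` with an added `class` column.
#' @export
classifyHits <- function(hits, secQueryPos, knownSet = character(),
                         knownSecPos = NULL) {
  hits$class <- vapply(seq_len(nrow(hits)), function(i)
    classifyHit(hits[i, ], secQueryPos, knownSet, knownSecPos), "")
  hits
}

#' Apply the homology retention rule
#'
#' A candidate is kept if (i) at least one hit anywhere in the (pre-filtered,
#' sorted) list is a Sec-containing homolog, or (ii) at least two of the
#' first ten hits are Cys-containing homologs with pairwise-distinct organism
#' tags. An empty hit list is rejected.
#'
#' @param hits Hit data.frame with columns `class` (from [classifyHits()]),
#'   `organism` and `sseqid`, already sorted by [searchHomologs()].
#' @return List with `keep` (logical), `reason` ("sec_homolog", "cys_rule" or
#'   "rejected") and `supporting` (subject ids of the supporting hits).
#' @export
applyRetentionRule <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(keep = FALSE, reason = "rejected", supporting = character()))
  sec <- which(hits$class == "sec_homolog")
  if (length(sec))
    return(list(keep = TRUE, reason = "sec_homolog",
                supporting = hits$sseqid[sec]))
  top <- head(hits, 10L)
  cys <- which(top$class == "cys_homolog")
  if (length(unique(top$organism[cys])) >= 2L)
    return(list(keep = TRUE, reason = "cys_rule",
                supporting = top$sseqid[cys]))
  list(keep = FALSE, reason = "rejected", supporting = character())
}

#' Label a retained candidate as a known selenoprotein homolog or new
#'
#' Known means a supporting Sec-homolog hit whose subject belongs to the
#' curated known-selenoprotein set; the family tag of the best (lowest
#' e-value) such hit wins. Candidates kept through the Cys rule alone are
#' "new".
#'
#' @param hits Classified hit data.frame.
#' @param decision Result of [applyRetentionRule()]; must have `keep = TRUE`.
#' @param knownSet Character vector of known-selenoprotein subject ids.
#' @return List with `status` ("known" or "new") and `family` (tag or NA).
#' @export
labelKnownOrNew <- function(hits, decision, knownSet = character()) {
  if (!isTRUE(decision$keep))
    stop("labelKnownOrNew() called on a rejected candidate")
  sec <- hits[hits$class == "sec_homolog" & hits$sseqid %in% knownSet, ,
              drop = FALSE]
  if (nrow(sec) == 0L) return(list(status = "new", family = NA_character_))
  best <- sec[order(sec$evalue, -sec$bitscore, sec$sseqid), , drop = FALSE][1L, ]
  fam <- if (!is.null(best$family) && !is.na(best$family)) best$family
         else .parse_family(best$sseqid)
  list(status = "known", family = fam)
}
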