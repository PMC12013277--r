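# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use a different formulation than the package code.

# position-by-position scan of both strands
brute_sites <- function(seq) {
  seq <- toupper(seq)
  rc <- reverseComplementString(seq)
  n <- nchar(seq)
  hit <- function(s) {
    pos <- integer()
    for (p in 0:(n - 3)) if (substr(s, p + 1, p + 3) == "TGA") pos <- c(pos, p)
    pos
  }
  plus <- if (n >= 3) hit(seq) else integer()
  minus <- if (n >= 3) hit(rc) else integer()
  df <- rbind(
    data.frame(strand = rep("+", length(plus)), pos = plus),
    data.frame(strand = rep("-", length(minus)), pos = minus))
  df[order(df$strand, df$pos), , drop = FALSE]
}

# set-logic reconstruction of the ORF around an in-frame TGA: enumerate all
# in-frame codons at once, locate the nearest upstream terminator barrier,
# pick the start relative to it, and the first downstream terminator
brute_orf <- function(s, pos, params = scanParams()) {
  n <- nchar(s)
  qs <- seq(pos %% 3, n - 3, by = 3)
  codons <- substring(s, qs + 1, qs + 3)
  term <- codons %in% params@terminatorSet
  start <- codons %in% c("ATG", "CTG", "GTG")
  up <- qs < pos
  barrier <- if (any(term & up)) max(qs[term & up]) else -Inf
  cand_starts <- qs[start & up & qs > barrier]
  if (!length(cand_starts)) return(NULL)
  start_pos <- if (params@startChoice == "farthest") min(cand_starts) else max(cand_starts)
  sec_idx <- (pos - start_pos) %/% 3
  if (sec_idx < params@minUpstreamCodons) return(NULL)
  down_terms <- qs[term & qs > pos]
  stop_pos <- if (length(down_terms)) min(down_terms) else NA_integer_
  orf_len <- if (is.na(stop_pos)) ((n - start_pos) %/% 3) * 3 else stop_pos + 3 - start_pos
  if (orf_len < params@minOrfLen) return(NULL)
  list(start_pos = start_pos, stop_pos = stop_pos, sec_codon_index = sec_idx,
       partial3 = is.na(stop_pos))
}

# whole-contig reverse-complement oracle for minus-strand windows
brute_window_minus <- function(contig_seq, pos, L) {
  rc <- reverseComplementString(contig_seq)
  from <- pos + 3
  avail <- nchar(rc) - from
  core <- if (avail > 0) substr(rc, from + 1, min(nchar(rc), from + L)) else ""
  if (avail >= L) core else paste0(core, strrep("N", L - max(avail, 0)))
}

# literal reading of the retention criteria over class/organism vectors
brute_retention <- function(classes, organisms) {
  if (any(classes == "sec_homolog")) return(TRUE)
  top <- seq_len(min(10, length(classes)))
  cys_orgs <- unique(organisms[top][classes[top] == "cys_homolog"])
  length(cys_orgs) >= 2
}

# hits table with given classes/organisms (payload fields arbitrary)
make_class_hits <- function(classes, organisms, evalues = NULL) {
  n <- length(classes)
  if (n == 0)
    return(data.frame(sseqid = character(), organism = character(),
                      class = character(), evalue = numeric(),
                      bitscore = numeric()))
  data.frame(sseqid = sprintf("s%02d", seq_len(n)), organism = organisms,
             class = classes,
             evalue = if (is.null(evalues)) seq_len(n) * 1e-5 else evalues,
             bitscore = rev(seq_len(n)), stringsAsFactors = FALSE)
}

# greedy clustering with a precomputed all-pairs identity/coverage table
brute_cluster <- function(seqs, idThreshold = 0.5, covThreshold = 0.8) {
  n <- length(seqs)
  idm <- matrix(0, n, n); cvq <- matrix(0, n, n); cvs <- matrix(0, n, n)
  for (i in seq_len(n)) {
    al <- selenoscan:::.align_nt(seqs[i], seqs)
    idm[i, ] <- al$identity; cvq[i, ] <- al$cov_query; cvs[i, ] <- al$cov_subject
  }
  ord <- order(-nchar(seqs), seqs)
  reps <- integer(); assignment <- integer(n)
  for (i in ord) {
    hitrep <- 0
    for (r in seq_along(reps)) {
      j <- reps[r]
      if (idm[i, j] >= idThreshold && cvq[i, j] >= covThreshold &&
          cvs[i, j] >= covThreshold) { hitrep <- r; break }
    }
    if (hitrep > 0) assignment[i] <- hitrep
    else { reps <- c(reps, i); assignment[i] <- length(reps) }
  }
  list(assignment = assignment, representatives = reps)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# independent table-driven translation (code fetched fresh from Biostrings)
brute_translate <- function(nt, sec_codon_index) {
  code <- Biostrings::getGeneticCode("11")
  codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa[codons == "TGA"] <- "X"
  aa[1] <- "M"
  aa[sec_codon_index + 1] <- "U"
  paste(aa, collapse = "")
}
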