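# Six-frame TGA scanning and ORF reconstruction. All coordinates are 0-based
# and strand-local: a minus-strand position is an offset into the
# reverse-complemented contig. Conversion to 1-based forward coordinates
# happens only at GFF3 export.

#' Read a genome FASTA
#'
#' Multi-record nucleotide FASTA (wrapped or single-line, CRLF tolerated).
#' Sequences are upper-cased on ingest; record ids are the first whitespace-
#' delimited word of each header.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with contig ids as names.
#' @export
readGenome <- function(path) {
  gn <- Biostrings::readDNAStringSet(path)
  names(gn) <- sub("\\s.*$", "", names(gn))
  gn
}

.as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(readGenome(genome))
  if (is.character(genome)) {
    gn <- Biostrings::DNAStringSet(toupper(genome))
    if (is.null(names(gn))) names(gn) <- paste0("contig_", seq_along(gn))
    return(gn)
  }
  stop("genome must be a DNAStringSet, a FASTA path, or a character vector")
}

#' Reverse complement of a nucleotide string
#'
#' Standard complement, reversed; IUPAC ambiguity codes map to their IUPAC
#' complements (N to N). Characters outside the IUPAC alphabet are an error.
#'
#' @param seq A single nucleotide string.
#' @return The reverse-complemented string.
#' @examples
#' reverseComplementString("ATGC")  # "GCAT"
#' @export
reverseComplementString <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

.strand_seq <- function(contig_seq, strand) {
  s <- as.character(contig_seq)
  if (strand == "-") reverseComplementString(s) else s
}

#' Enumerate TGA triplets in all six reading frames
#'
#' Every position, on both strands, where the strand-forward triplet is
#' exactly TGA. Ambiguity codes never match. Positions are 0-based and
#' strand-local; `frame` is `pos %% 3` on that strand.
#'
#' @param genome A [Biostrings::DNAStringSet], FASTA path, or character vector.
#' @return A data.frame with columns contig, strand, pos, frame, sorted by
#'   (contig, strand, pos). Empty genomes give zero rows.
#' @examples
#' enumerateTgaSites(c(chr = "ATGAAATGAGGGTAA"))
#' @export
enumerateTgaSites <- function(genome) {
  genome <- .as_genome(genome)
  out <- vector("list", 2L * length(genome))
  j <- 0L
  for (i in seq_along(genome)) {
    contig <- names(genome)[i]
    len <- Biostrings::width(genome)[i]
    plus <- Biostrings::start(Biostrings::matchPattern(
      "TGA", genome[[i]], fixed = TRUE)) - 1L
    # a minus-strand TGA is a forward-strand TCA; its strand-local position is
    # len - forward_pos - 3
    tca <- Biostrings::start(Biostrings::matchPattern(
      "TCA", genome[[i]], fixed = TRUE)) - 1L
    minus <- sort(len - tca - 3L)
    j <- j + 1L
    out[[j]] <- data.frame(contig = rep(contig, length(plus)),
                           strand = rep("+", length(plus)),
                           pos = plus, stringsAsFactors = FALSE)
    j <- j + 1L
    out[[j]] <- data.frame(contig = rep(contig, length(minus)),
                           strand = rep("-", length(minus)),
                           pos = minus, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, out[seq_len(j)])
  if (is.null(sites) || nrow(sites) == 0L)
    return(data.frame(contig = character(), strand = character(),
                      pos = integer(), frame = integer()))
  sites <- sites[order(sites$contig, sites$strand, sites$pos), , drop = FALSE]
  sites$frame <- sites$pos %% 3L
  rownames(sites) <- NULL
  sites
}

.codon_at <- function(s, pos0) substr(s, pos0 + 1L, pos0 + 3L)

#' Reconstruct the candidate ORF around an in-frame TGA
#'
#' Walks upstream from the TGA in codon steps, keeping the farthest (or
#' nearest, per `startChoice`) in-frame start codon (ATG, CTG or GTG) not
#' separated from the TGA by a terminator codon, and downstream to the first
#' in-frame terminator. Returns `NULL` when no in-frame start exists, fewer
#' than `minUpstreamCodons` codons precede the TGA, or the ORF is shorter
#' than `minOrfLen`.
#'
#' @param genome Genome as in [enumerateTgaSites()].
#' @param contig Contig id.
#' @param strand "+" or "-".
#' @param pos 0-based strand-local position of the T of the TGA triplet.
#' @param params A [ScanParams-class] object.
#' @return One-row data.frame (contig, strand, start_pos, tga_pos, stop_pos,
#'   sec_codon_index, partial3, orf_len) or `NULL`. `stop_pos` is NA and
#'   `partial3` TRUE when the ORF runs off the contig.
#' @examples
#' findCandidateOrf(c(chr = "ATGAAATGAGGGTAA"), "chr", "+", 6,
#'                  scanParams(minUpstreamCodons = 0, minOrfLen = 0))
#' @export
findCandidateOrf <- function(genome, contig, strand, pos, params = scanParams()) {
  genome <- .as_genome(genome)
  s <- .strand_seq(genome[[contig]], strand)
  .find_orf_strand(s, contig, strand, pos, params)
}

.find_orf_strand <- function(s, contig, strand, pos, params) {
  n <- nchar(s)
  if (pos < 0L || pos + 3L > n || .codon_at(s, pos) != "TGA")
    stop("site at ", contig, ":", strand, ":", pos, " is not a TGA triplet")
  term <- params@terminatorSet
  nearest <- params@startChoice == "nearest"

  start_pos <- NA_integer_
  q <- pos - 3L
  while (q >= 0L) {
    cod <- .codon_at(s, q)
    if (cod %in% term) break
    if (cod %in% START_CODONS) {
      start_pos <- q
      if (nearest) break
    }
    q <- q - 3L
  }
  if (is.na(start_pos)) return(NULL)

  sec_idx <- (pos - start_pos) %/% 3L
  if (sec_idx < params@minUpstreamCodons) return(NULL)

  stop_pos <- NA_integer_
  q <- pos + 3L
  while (q + 3L <= n) {
    if (.codon_at(s, q) %in% term) { stop_pos <- q; break }
    q <- q + 3L
  }
  partial3 <- is.na(stop_pos)
  orf_len <- if (partial3) ((n - start_pos) %/% 3L) * 3L else stop_pos + 3L - start_pos
  if (orf_len < params@minOrfLen) return(NULL)

  data.frame(contig = contig, strand = strand, start_pos = start_pos,
             tga_pos = pos, stop_pos = stop_pos, sec_codon_index = sec_idx,
             partial3 = partial3, orf_len = orf_len, stringsAsFactors = FALSE)
}

#' Extract the fixed-length window downstream of a TGA
#'
#' The window starts at the first nucleotide after the TGA triplet, in strand
#' coordinates. Windows running off the contig are padded with 'N' when
#' `padShortWindows` is set (k-mers containing 'N' later map to UNK), else
#' dropped.
#'
#' @inheritParams findCandidateOrf
#' @return A list with `seq` (length `windowLen`) and `n_padded`, or `NULL`.
#' @export
extractDownstreamWindow <- function(genome, contig, strand, pos,
                                    params = scanParams()) {
  genome <- .as_genome(genome)
  s <- .strand_seq(genome[[contig]], strand)
  .window_strand(s, pos, params)
}

.window_strand <- function(s, pos, params) {
  L <- params@windowLen
  n <- nchar(s)
  from <- pos + 3L
  avail <- n - from
  if (avail >= L)
    return(list(seq = substr(s, from + 1L, from + L), n_padded = 0L))
  if (!params@padShortWindows) return(NULL)
  core <- if (avail > 0L) substr(s, from + 1L, n) else ""
  list(seq = paste0(core, strrep("N", L - max(avail, 0L))),
       n_padded = L - max(avail, 0L))
}

#' Scan a genome for candidate selenoprotein ORFs
#'
#' Runs site enumeration, ORF reconstruction and window extraction for every
#' TGA site. Deterministic: the same genome and parameters always yield
#' byte-identical output.
#'
#' @inheritParams enumerateTgaSites
#' @param params A [ScanParams-class] object.
#' @return A list with `sites` (all TGA sites) and `orfs`: one row per valid
#'   candidate ORF with its downstream window (`window`, `n_padded`).
#' @export
scanGenome <- function(genome, params = scanParams()) {
  genome <- .as_genome(genome)
  sites <- enumerateTgaSites(genome)
  if (nrow(sites) == 0L)
    return(list(sites = sites, orfs = data.frame()))
  strand_cache <- new.env(parent = emptyenv())
  get_s <- function(contig, strand) {
    key <- paste0(contig, strand)
    if (is.null(strand_cache[[key]]))
      strand_cache[[key]] <- .strand_seq(genome[[contig]], strand)
    strand_cache[[key]]
  }
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- get_s(sites$contig[i], sites$strand[i])
    orf <- .find_orf_strand(s, sites$contig[i], sites$strand[i],
                            sites$pos[i], params)
    if (is.null(orf)) next
    w <- .window_strand(s, sites$pos[i], params)
    if (is.null(w)) next
    orf$window <- w$seq
    orf$n_padded <- w$n_padded
    rows[[i]] <- orf
  }
  orfs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(orfs)) orfs <- data.frame()
  rownames(orfs) <- NULL
  list(sites = sites, orfs = orfs)
}

#' Write a site or ORF table as TSV
#'
#' @param x Data.frame from [enumerateTgaSites()] or [scanGenome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
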