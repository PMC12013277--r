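# k-mer tokenization and integer encoding of downstream windows.

#' Build a k-mer vocabulary
#'
#' Five special tokens (ids 0..4: PAD, UNK, CLS, SEP, MASK) followed by all
#' 4^k ACGT k-mers in lexicographic order.
#'
#' @param k k-mer size, one of 3, 4, 5.
#' @return A [KmerVocab-class].
#' @examples
#' vocabSize(buildVocab(3))  # 69
#' @export
buildVocab <- function(k) {
  k <- as.integer(k)
  if (!k %in% 3:5) stop("k must be 3, 4 or 5")
  kmers <- sort(do.call(paste0, expand.grid(
    rep(list(c("A", "C", "G", "T")), k), stringsAsFactors = FALSE)))
  tokens <- c(SPECIAL_TOKENS, kmers)
  new("KmerVocab", k = k, tokens = tokens,
      index = setNames(seq_along(tokens) - 1L, tokens))
}

.PAD <- 0L; .UNK <- 1L; .CLS <- 2L; .SEP <- 3L; .MASK <- 4L

#' Tokenize a nucleotide sequence into overlapping k-mers
#'
#' Sliding window with stride 1, so a sequence of length L yields L - k + 1
#' tokens. Any k-mer containing a non-ACGT character becomes the UNK token,
#' keeping positions aligned.
#'
#' @param seq A single nucleotide string with at least k characters.
#' @param k k-mer size.
#' @return Character vector of tokens.
#' @examples
#' kmerize("ATGCA", 3)  # "ATG" "TGC" "GCA"
#' @export
kmerize <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k")
  starts <- seq_len(n - k + 1L)
  toks <- substring(seq, starts, starts + k - 1L)
  toks[grepl("[^ACGT]", toks)] <- "[UNK]"
  toks
}

#' Encode windows as padded integer id matrices
#'
#' Each window is tokenized, wrapped as [CLS] tokens [SEP], and right-padded
#' with PAD up to `maxLen`. The attention mask is 1 for real tokens (CLS and
#' SEP included) and 0 for PAD. Token sequences longer than `maxLen - 2` are
#' an error, never silently truncated.
#'
#' @param seqs Character vector of windows (or a list of token vectors).
#' @param vocab A [KmerVocab-class].
#' @param maxLen Encoded length; defaults to tokens-of-longest-window + 2.
#' @return List with integer matrices `ids` and `mask` (n x maxLen, 0-based
#'   ids) and the vocabulary as attribute `k`.
#' @export
encodeWindows <- function(seqs, vocab, maxLen = NULL) {
  tok_list <- if (is.list(seqs)) seqs else lapply(seqs, kmerize, k = vocab@k)
  lens <- lengths(tok_list)
  if (is.null(maxLen)) maxLen <- max(lens) + 2L
  if (any(lens > maxLen - 2L))
    stop("token sequence exceeds maxLen - 2; refusing to truncate")
  n <- length(tok_list)
  ids <- matrix(.PAD, n, maxLen)
  mask <- matrix(0L, n, maxLen)
  for (i in seq_len(n)) {
    v <- unname(vocab@index[tok_list[[i]]])
    v[is.na(v)] <- .UNK
    row <- c(.CLS, v, .SEP)
    ids[i, seq_along(row)] <- row
    mask[i, seq_along(row)] <- 1L
  }
  storage.mode(ids) <- "integer"
  list(ids = ids, mask = mask, k = vocab@k)
}

#' Decode id rows back to k-mer tokens
#'
#' Inverse of [encodeWindows()] on the non-special tokens: special ids (PAD,
#' CLS, SEP, MASK) are dropped, UNK decodes to the UNK token.
#'
#' @param ids Integer matrix or vector of 0-based ids.
#' @param vocab A [KmerVocab-class].
#' @return A list of token vectors (or a single vector for vector input).
#' @export
decodeIds <- function(ids, vocab) {
  dec1 <- function(v) {
    toks <- vocab@tokens[v + 1L]
    toks[!toks %in% SPECIAL_TOKENS[c(1, 3, 4, 5)]]
  }
  if (is.matrix(ids)) lapply(seq_len(nrow(ids)), function(i) dec1(ids[i, ]))
  else dec1(ids)
}

#' Write / read a vocabulary as a token-per-line text file
#'
#' Ids are implicit in line order (line 1 is id 0).
#'
#' @param vocab A [KmerVocab-class].
#' @param path File path.
#' @return `path` invisibly (write); a [KmerVocab-class] (read).
#' @export
writeVocab <- function(vocab, path) {
  writeLines(vocab@tokens, path)
  invisible(path)
}

#' @rdname writeVocab
#' @export
readVocab <- function(path) {
  tokens <- readLines(path)
  k <- nchar(tokens[length(tokens)])
  new("KmerVocab", k = as.integer(k), tokens = tokens,
      index = setNames(seq_along(tokens) - 1L, tokens))
}
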