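# Seeded synthetic data with known ground truth: labeled window corpora,
# genomes with planted selenoprotein genes and stop-TGA decoys, and matched
# fixture protein databases. The downstream signal is a position weight
# matrix emitted at a fixed offset after the TGA — a stand-in for the
# bacterial SECIS element (the classifier contract only needs a learnable
# downstream signal; no secondary structure is modeled).

.BASES <- c("A", "C", "G", "T")

.bg_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                            T = (1 - gc) / 2)

.rand_nt <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE, prob = .bg_probs(gc)), collapse = "")
}

#' Position weight matrix of the planted motif
#'
#' Each column puts `strength + (1 - strength) * bg` probability on the
#' consensus base and background-proportional mass on the rest, so strength 0
#' is indistinguishable from background and strength 1 is deterministic.
#'
#' @param cfg A [SimConfig-class].
#' @return A 4 x motif-length matrix with rows A, C, G, T summing to 1.
#' @export
motifPWM <- function(cfg) {
  cons <- strsplit(cfg@motifConsensus, "")[[1]]
  bg <- .bg_probs(cfg@gcContent)
  pwm <- vapply(cons, function(b) {
    p <- (1 - cfg@motifStrength) * bg
    p[b] <- p[b] + cfg@motifStrength
    p
  }, numeric(4))
  rownames(pwm) <- .BASES
  pwm
}

.sample_motif <- function(pwm) {
  paste(apply(pwm, 2, function(p) sample(.BASES, 1L, prob = p)), collapse = "")
}

.plant_motif <- function(window, cfg, pwm) {
  m <- .sample_motif(pwm)
  substr(window, cfg@motifOffset + 1L, cfg@motifOffset + nchar(m)) <- m
  window
}

#' Generate a labeled synthetic window corpus
#'
#' Positives are drawn per family: each family has a background prototype;
#' members are the prototype with per-position mutation rate `mutRate`
#' (keeping within-family identity high and between-family identity at
#' background levels, so clustering and identity-capped splits have
#' structure to find), with the motif re-sampled from the PWM per member.
#' Negatives are i.i.d. background. Class sizes are equal.
#'
#' @param cfg A [SimConfig-class]; `motifStrength`, `gcContent` and `seed`
#'   are taken from it.
#' @param n Windows per class (default 2000).
#' @param windowLen Window length (default 300).
#' @param nFamilies Number of positive families (default 75).
#' @param mutRate Per-position mutation rate within a family (default 0.1).
#' @return Data.frame (seq, label, family, organism).
#' @export
simulateCorpus <- function(cfg, n = 2000L, windowLen = 300L, nFamilies = 75L,
                           mutRate = 0.1) {
  if (cfg@motifOffset + nchar(cfg@motifConsensus) > windowLen)
    stop("motif does not fit in the window")
  set.seed(cfg@seed)
  pwm <- motifPWM(cfg)
  bg <- .bg_probs(cfg@gcContent)

  protos <- vapply(seq_len(nFamilies), function(i) .rand_nt(windowLen, cfg@gcContent), "")
  fam_of <- rep_len(seq_len(nFamilies), n)
  pos <- character(n)
  for (i in seq_len(n)) {
    w <- strsplit(protos[fam_of[i]], "")[[1]]
    mut <- runif(windowLen) < mutRate
    if (any(mut)) w[mut] <- sample(.BASES, sum(mut), replace = TRUE, prob = bg)
    pos[i] <- .plant_motif(paste(w, collapse = ""), cfg, pwm)
  }
  neg <- vapply(seq_len(n), function(i) .rand_nt(windowLen, cfg@gcContent), "")
  data.frame(
    seq = c(pos, neg),
    label = rep(c("pos", "neg"), each = n),
    family = c(sprintf("fam%03d", fam_of), rep(NA_character_, n)),
    organism = c(sprintf("simorg%03d", 1L + (seq_len(n) %% 20L)),
                 sprintf("negorg%03d", 1L + (seq_len(n) %% 20L))),
    stringsAsFactors = FALSE)
}

.nonstop_codons <- function() {
  if (is.null(.cache$nonstop)) {
    all3 <- do.call(paste0, expand.grid(rep(list(.BASES), 3),
                                        stringsAsFactors = FALSE))
    .cache$nonstop <- setdiff(all3, c("TAA", "TAG", "TGA"))
  }
  .cache$nonstop
}

.rand_codons <- function(n) paste(sample(.nonstop_codons(), n, replace = TRUE),
                                  collapse = "")

# One planted gene in gene orientation, framed by an in-frame upstream TAA so
# the reconstructed ORF start is exactly the planted ATG. Returns the
# fragment plus gene coordinates within it.
.make_gene <- function(cfg, pwm, type = c("sec", "decoy")) {
  type <- match.arg(type)
  for (attempt in 1:80) {
    n_up <- sample(15:40, 1L)
    if (type == "sec") {
      n_down <- sample(40:80, 1L)
      down <- .rand_codons(n_down)
      m <- .sample_motif(pwm)
      substr(down, cfg@motifOffset + 1L, cfg@motifOffset + nchar(m)) <- m
      body <- paste0("ATG", .rand_codons(n_up - 1L), "TGA", down, "TAA")
    } else {
      body <- paste0("ATG", .rand_codons(n_up - 1L), "TGA")
    }
    tga_body <- 3L * n_up  # offset of the TGA within the body
    frag <- paste0("TAA", body)
    # validate the reading frame: no unintended in-frame stops
    codons <- substring(body, seq(1L, nchar(body) - 2L, 3L),
                        seq(3L, nchar(body), 3L))
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    want <- if (type == "sec") c(n_up + 1L, length(codons)) else n_up + 1L
    if (identical(stops, as.integer(want)))
      return(list(frag = frag, start_rel = 3L, tga_rel = 3L + tga_body,
                  stop_rel = if (type == "sec") nchar(frag) - 3L else NA_integer_))
  }
  stop("gene placement failed after bounded retries")
}

#' Generate a synthetic genome with planted selenoprotein genes
#'
#' Plants `nSelenogenes` valid selenoprotein ORFs (ATG start, in-frame TGA
#' with the motif downstream, TAA terminator) and `nDecoyGenes` decoy ORFs
#' that genuinely end with a stop-TGA and carry no motif, at non-overlapping
#' loci on both strands of a random background. Each gene is preceded by an
#' in-frame TAA so the reconstructed ORF matches the planted coordinates
#' exactly.
#'
#' @param cfg A [SimConfig-class].
#' @return List with `genome` (single-contig
#'   [Biostrings::DNAStringSet]) and `truth`: one row per planted gene
#'   (gene_id, type, contig, strand, start, tga_pos, stop, family,
#'   has_db_homolog) in 0-based strand-local coordinates.
#' @export
simulateGenome <- function(cfg) {
  set.seed(cfg@seed)
  pwm <- motifPWM(cfg)
  n_genes <- cfg@nSelenogenes + cfg@nDecoyGenes
  genes <- c(lapply(seq_len(cfg@nSelenogenes), function(i) .make_gene(cfg, pwm, "sec")),
             lapply(seq_len(cfg@nDecoyGenes), function(i) .make_gene(cfg, pwm, "decoy")))
  lens <- vapply(genes, function(g) nchar(g$frag), 1L)

  L <- cfg@genomeLen
  # non-overlapping placement with clearance for the downstream window:
  # allocate the slack directly as random inter-gene gaps
  gap <- 350L
  slack <- L - sum(lens) - n_genes * gap - 400L
  if (slack < 0L) stop("placement failure: genome too small for gene load")
  u <- diff(c(0, sort(runif(n_genes))))
  extra <- as.integer(floor(u * slack))
  ord <- sample.int(n_genes)  # interleave selenogenes and decoys along the contig
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    pos <- pos + gap + extra[i]
    starts[ord[i]] <- pos
    pos <- pos + lens[ord[i]]
  }
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)

  bg <- strsplit(.rand_nt(L, cfg@gcContent), "")[[1]]
  truth <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g <- genes[[i]]
    frag <- if (strands[i] == "+") g$frag else reverseComplementString(g$frag)
    o <- starts[i]
    bg[(o + 1L):(o + nchar(frag))] <- strsplit(frag, "")[[1]]
    # strand-local coordinates of the gene-orientation fragment
    base <- if (strands[i] == "+") o else L - o - nchar(g$frag)
    type <- if (i <= cfg@nSelenogenes) "sec" else "decoy"
    truth[[i]] <- data.frame(
      gene_id = sprintf("%s_%03d", type, i),
      type = type, contig = "contig_1", strand = strands[i],
      start = base + g$start_rel, tga_pos = base + g$tga_rel,
      stop = if (is.na(g$stop_rel)) NA_integer_ else base + g$stop_rel,
      family = if (type == "sec") sprintf("fam%03d", i) else NA_character_,
      has_db_homolog = type == "sec",
      stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(paste(bg, collapse = ""))
  names(genome) <- "contig_1"
  list(genome = genome, truth = do.call(rbind, truth))
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a fixture protein database matched to a synthetic genome
#'
#' For every planted selenoprotein gene with `has_db_homolog`, emits
#' `nHomologs` Cys-variant homologs (U replaced by C, then 5-15% random
#' substitutions away from the Sec column) under distinct organism tags, plus
#' optionally a Sec-containing entry for the first `nKnownFamilies` families
#' (members of the curated known-selenoprotein set). Decoy genes get no
#' homologs; `nDecoyProteins` unrelated random proteins pad the database.
#' Headers follow the "id|organism|family" dialect.
#'
#' @param sim Result of [simulateGenome()].
#' @param cfg The same [SimConfig-class].
#' @param nHomologs Cys-homologs per selenoprotein family (default 3).
#' @param nKnownFamilies Families that also get a Sec-containing known entry
#'   (default 2).
#' @param nDecoyProteins Unrelated database entries (default 30).
#' @return List with `db` ([Biostrings::AAStringSet]), `knownSet` (ids of
#'   known Sec-containing entries) and `knownSecPos` (their annotated Sec
#'   positions).
#' @export
simulateFixtureDb <- function(sim, cfg, nHomologs = 3L, nKnownFamilies = 2L,
                              nDecoyProteins = 30L) {
  set.seed(cfg@seed + 7L)
  truth <- sim$truth[sim$truth$type == "sec", , drop = FALSE]
  seqs <- character(); ids <- character()
  known_ids <- character(); known_pos <- integer()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    orf <- data.frame(contig = tr$contig, strand = tr$strand,
                      start_pos = tr$start, tga_pos = tr$tga_pos,
                      stop_pos = tr$stop,
                      sec_codon_index = (tr$tga_pos - tr$start) %/% 3L,
                      partial3 = is.na(tr$stop))
    prot <- translateOrf(sim$genome, orf)
    if (!tr$has_db_homolog) next
    aa <- strsplit(prot$protein, "")[[1]]
    for (h in seq_len(nHomologs)) {
      v <- aa
      v[prot$sec_index] <- "C"
      rate <- runif(1, 0.05, 0.15)
      mut <- which(runif(length(v)) < rate)
      mut <- setdiff(mut, prot$sec_index)
      if (length(mut)) v[mut] <- sample(.AA20, length(mut), replace = TRUE)
      ids <- c(ids, sprintf("hom_%03d_%d|org_%02d|%s", i, h, h, tr$family))
      seqs <- c(seqs, paste(v, collapse = ""))
    }
    if (i <= nKnownFamilies) {
      id <- sprintf("known_%03d|reforg_%02d|%s", i, i, tr$family)
      ids <- c(ids, id)
      seqs <- c(seqs, prot$protein)
      known_ids <- c(known_ids, id)
      known_pos <- c(known_pos, prot$sec_index)
    }
  }
  for (j in seq_len(nDecoyProteins)) {
    ids <- c(ids, sprintf("rand_%03d|bgorg_%02d|none", j, 1L + j %% 10L))
    seqs <- c(seqs, paste(sample(.AA20, sample(80:150, 1L), replace = TRUE),
                          collapse = ""))
  }
  db <- Biostrings::AAStringSet(seqs)
  names(db) <- ids
  list(db = db, knownSet = known_ids,
       knownSecPos = setNames(known_pos, known_ids))
}
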