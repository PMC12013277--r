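orf_row <- function(contig, strand, start, tga, stop, partial = FALSE) {
  data.frame(contig = contig, strand = strand, start_pos = start,
             tga_pos = tga, stop_pos = stop,
             sec_codon_index = (tga - start) %/% 3, partial3 = partial)
}

test_that("ORF translation uses table 11 with M start and U at the Sec codon", {
  g <- c(chr = "ATGTGTTGAGCCTAA")
  tr <- translateOrf(g, orf_row("chr", "+", 0, 6, 12))
  expect_equal(tr$protein, "MCUA")
  expect_equal(tr$sec_index, 3L)
  # alternative start codons still yield a leading M
  g2 <- c(chr = "GTGTGTTGAGCCTAA")
  expect_equal(translateOrf(g2, orf_row("chr", "+", 0, 6, 12))$protein, "MCUA")
  g3 <- c(chr = "CTGTGTTGAGCCTAA")
  expect_equal(translateOrf(g3, orf_row("chr", "+", 0, 6, 12))$protein, "MCUA")
  # an internal TAA violates the ORF contract
  g4 <- c(chr = "ATGTAATGAGCCTAA")
  expect_error(translateOrf(g4, orf_row("chr", "+", 0, 6, 12)), "contract")
})

test_that("translation of scanned ORFs matches an independent codon-table oracle", {
  set.seed(30)
  p <- scanParams(minUpstreamCodons = 3, minOrfLen = 30, windowLen = 100)
  n_checked <- 0
  for (i in 1:20) {
    g <- c(chr = random_dna(1200))
    scan <- scanGenome(g, p)
    if (!nrow(scan$orfs)) next
    for (j in seq_len(min(5, nrow(scan$orfs)))) {
      o <- scan$orfs[j, ]
      if (is.na(o$stop_pos)) next
      got <- translateOrf(g, o)
      s <- if (o$strand == "+") g[["chr"]] else reverseComplementString(g[["chr"]])
      nt <- substr(s, o$start_pos + 1, o$stop_pos)
      expect_equal(got$protein, brute_translate(nt, o$sec_codon_index))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("the built-in backend finds an exact Cys-variant at 100% identity", {
  prot <- "MAGKLUVWTESTPROTEINSEQKLMNADEFGHIKLWW"
  prot <- gsub("[BJOXZ]", "A", prot)
  cvar <- gsub("U", "C", prot, fixed = TRUE)
  db <- Biostrings::AAStringSet(c("exact|orgA|fam1" = cvar))
  hits <- searchHomologs(prot, db = db)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pident, 100)
  expect_equal(hits$organism, "orgA")
  # the aligned query string carries the restored U
  expect_true(grepl("U", hits$qseq_aln))
  expect_false(grepl("U", cvar))
})

test_that("hits violating the e-value or identity thresholds are excluded", {
  base <- data.frame(qseqid = "q", sseqid = c("a|o1|f", "b|o2|f", "c|o3|f"),
                     pident = c(80, 15, 90), evalue = c(1e-10, 1e-10, 0.5),
                     bitscore = c(50, 50, 10), qstart = 1, qend = 10,
                     sstart = 1, send = 10, qseq_aln = "AAAAAAAAAA",
                     sseq_aln = "AAAAAAAAAA", organism = c("o1", "o2", "o3"))
  out <- searchHomologs("MAUA", hits = base, qseqid = "q")
  expect_equal(out$sseqid, "a|o1|f")   # pident 15 and evalue 0.5 both dropped
})

test_that("hit classification reads the residue aligned to the Sec position", {
  hit <- function(qa, sa, qstart = 1, sstart = 1, sid = "s|o|f")
    list(qseqid = "q", sseqid = sid, qstart = qstart,
         qend = qstart + sum(strsplit(qa, "")[[1]] != "-") - 1,
         sstart = sstart, qseq_aln = qa, sseq_aln = sa)
  expect_equal(classifyHit(hit("MAUK", "MACK"), 3), "cys_homolog")
  expect_equal(classifyHit(hit("MAUK", "MAUK"), 3), "sec_homolog")
  expect_equal(classifyHit(hit("MAUK", "MA-K"), 3), "other")
  expect_equal(classifyHit(hit("MAUK", "MAGK"), 3), "other")
  # gapped query shifts the column: U is query pos 3, column 4
  expect_equal(classifyHit(hit("MA-UK", "MAGCK"), 3), "cys_homolog")
  # Sec outside the aligned span
  expect_equal(classifyHit(hit("AUK", "ACK", qstart = 2), 10), "other")
  # curated known selenoprotein with annotated Sec aligned at that column
  h <- hit("MAUK", "MACK", sid = "known1")
  expect_equal(classifyHit(h, 3, knownSet = "known1",
                           knownSecPos = c(known1 = 3L)), "sec_homolog")
})

test_that("the retention rule follows both criteria on canonical cases", {
  d <- applyRetentionRule(make_class_hits("sec_homolog", "o1"))
  expect_true(d$keep); expect_equal(d$reason, "sec_homolog")
  d <- applyRetentionRule(make_class_hits(c("cys_homolog", "cys_homolog"),
                                          c("o1", "o2")))
  expect_true(d$keep); expect_equal(d$reason, "cys_rule")
  d <- applyRetentionRule(make_class_hits(c("cys_homolog", "cys_homolog"),
                                          c("o1", "o1")))
  expect_false(d$keep)
  expect_false(applyRetentionRule(make_class_hits(character(), character()))$keep)
  # a Sec homolog counts anywhere in the list, beyond the top ten
  cls <- c(rep("other", 11), "sec_homolog")
  d <- applyRetentionRule(make_class_hits(cls, paste0("o", 1:12)))
  expect_true(d$keep); expect_equal(d$reason, "sec_homolog")
  # Cys homologs only count within the top ten
  cls <- c(rep("other", 10), "cys_homolog", "cys_homolog")
  expect_false(applyRetentionRule(make_class_hits(cls, paste0("o", 1:12)))$keep)
})

test_that("the retention rule is monotone and ignores payload fields", {
  set.seed(31)
  classes <- c("sec_homolog", "cys_homolog", "other")
  for (i in 1:200) {
    n <- sample(0:12, 1)
    cls <- sample(classes, n, replace = TRUE, prob = c(0.15, 0.45, 0.4))
    org <- sample(paste0("o", 1:3), n, replace = TRUE)
    h <- make_class_hits(cls, org)
    d <- applyRetentionRule(h)
    # adding a sec homolog never flips keep -> reject
    h2 <- rbind(h, make_class_hits("sec_homolog", "oX"))
    expect_true(applyRetentionRule(h2)$keep)
    # removing hits never flips reject -> keep
    if (!d$keep && n > 0) {
      h3 <- h[-sample(n, 1), , drop = FALSE]
      expect_false(applyRetentionRule(h3)$keep)
    }
    # shuffling payload (evalue/bitscore/ids) leaves the decision unchanged
    h4 <- h
    if (n > 0) {
      h4$evalue <- rev(h4$evalue)
      h4$bitscore <- sample(h4$bitscore)
      expect_equal(applyRetentionRule(h4)$keep, d$keep)
    }
  }
})

test_that("known/new labeling follows the supporting Sec homologs", {
  h <- make_class_hits(c("sec_homolog", "cys_homolog"), c("o1", "o2"))
  h$family <- c("famA", "famB")
  d <- applyRetentionRule(h)
  expect_equal(labelKnownOrNew(h, d, knownSet = "s01"),
               list(status = "known", family = "famA"))
  expect_equal(labelKnownOrNew(h, d, knownSet = character())$status, "new")
  # kept through the Cys rule alone: new
  h2 <- make_class_hits(c("cys_homolog", "cys_homolog"), c("o1", "o2"))
  d2 <- applyRetentionRule(h2)
  expect_equal(labelKnownOrNew(h2, d2, knownSet = "s01")$status, "new")
  # two known Sec homologs from different families: lowest e-value wins
  h3 <- make_class_hits(c("sec_homolog", "sec_homolog"), c("o1", "o2"),
                        evalues = c(1e-3, 1e-8))
  h3$family <- c("famA", "famB")
  d3 <- applyRetentionRule(h3)
  expect_equal(labelKnownOrNew(h3, d3, knownSet = c("s01", "s02"))$family, "famB")
  expect_error(labelKnownOrNew(h, list(keep = FALSE), "s01"), "rejected")
})

test_that("hit tables round-trip through the TSV dialect", {
  h <- data.frame(qseqid = "q", sseqid = "s|o|f", pident = 88.5,
                  evalue = 1e-12, bitscore = 60.2, qstart = 1L, qend = 40L,
                  sstart = 3L, send = 42L, qseq_aln = "MAU-K",
                  sseq_aln = "MACLK", organism = "o")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeHitsTable(h, path)
  h2 <- readHitsTable(path)
  expect_equal(h2$pident, 88.5)
  expect_equal(h2$qseq_aln, "MAU-K")
  expect_error(readHitsTable(writeHitsTable(h[, 1:5], path)), "lacks")
})
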