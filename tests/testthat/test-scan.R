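test_that("reverse complement follows IUPAC rules and is an involution", {
  expect_equal(reverseComplementString("ATGC"), "GCAT")
  expect_equal(reverseComplementString("TGA"), "TCA")
  expect_equal(reverseComplementString("NRY"), "RYN")
  expect_error(reverseComplementString("ATZ"))
  set.seed(1)
  for (i in 1:20) {
    s <- random_dna(1000)
    expect_identical(reverseComplementString(reverseComplementString(s)), s)
  }
})

test_that("single-triplet genomes are sited on the correct strand", {
  s <- enumerateTgaSites(c(x = "TGA"))
  expect_equal(nrow(s), 1L)
  expect_equal(s$strand, "+")
  expect_equal(s$pos, 0L)
  s <- enumerateTgaSites(c(x = "TCA"))
  expect_equal(nrow(s), 1L)
  expect_equal(s$strand, "-")
  expect_equal(s$pos, 0L)
  expect_equal(nrow(enumerateTgaSites(c(x = "AAAA"))), 0L)
})

test_that("site enumeration matches a brute-force scan on random sequences", {
  set.seed(7)
  for (i in 1:30) {
    g <- random_dna(2000)
    got <- enumerateTgaSites(c(chr = g))
    want <- brute_sites(g)
    expect_equal(got$strand, want$strand)
    expect_equal(got$pos, want$pos)
    # linear-contig count identity: TGA forward + TCA forward
    n_tga <- lengths(regmatches(g, gregexpr("(?=TGA)", g, perl = TRUE)))
    n_tca <- lengths(regmatches(g, gregexpr("(?=TCA)", g, perl = TRUE)))
    expect_equal(nrow(got), n_tga + n_tca)
  }
})

test_that("site enumeration is strand-symmetric under reverse complement", {
  set.seed(8)
  for (i in 1:10) {
    g <- random_dna(1500)
    a <- enumerateTgaSites(c(chr = g))
    b <- enumerateTgaSites(c(chr = reverseComplementString(g)))
    swap <- b
    swap$strand <- ifelse(b$strand == "+", "-", "+")
    swap <- swap[order(swap$strand, swap$pos), ]
    expect_equal(swap$strand, a$strand)
    expect_equal(swap$pos, a$pos)
  }
})

test_that("ORF reconstruction recovers the worked example", {
  g <- c(chr = "ATGAAATGAGGGTAA")
  p0 <- scanParams(minUpstreamCodons = 0, minOrfLen = 0)
  orf <- findCandidateOrf(g, "chr", "+", 6, p0)
  expect_equal(orf$start_pos, 0L)
  expect_equal(orf$stop_pos, 12L)
  expect_equal(orf$sec_codon_index, 2L)
  expect_false(orf$partial3)
  # in-frame terminator between every start and the TGA blocks the ORF
  g2 <- c(chr = "ATGTAAATGTAAGGGTGAGGGTAA")
  expect_null(findCandidateOrf(g2, "chr", "+", 15, p0))
  # non-TGA site violates the contract
  expect_error(findCandidateOrf(g, "chr", "+", 0, p0), "not a TGA")
})

test_that("ORF reconstruction agrees with the set-logic oracle on random layouts", {
  set.seed(9)
  p0 <- scanParams(minUpstreamCodons = 0, minOrfLen = 0)
  p1 <- scanParams(minUpstreamCodons = 5, minOrfLen = 60)
  checked <- 0
  for (i in 1:60) {
    s <- random_dna(600)
    sites <- enumerateTgaSites(c(chr = s))
    sites <- sites[sites$strand == "+", ]
    if (!nrow(sites)) next
    for (pos in sites$pos) {
      for (p in list(p0, p1)) {
        got <- findCandidateOrf(c(chr = s), "chr", "+", pos, p)
        want <- brute_orf(s, pos, p)
        if (is.null(want)) {
          expect_null(got)
        } else {
          expect_equal(got$start_pos, want$start_pos)
          expect_equal(got$sec_codon_index, want$sec_codon_index)
          if (is.na(want$stop_pos)) expect_true(got$partial3)
          else expect_equal(got$stop_pos, want$stop_pos)
        }
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 200)
})

test_that("nearest-start convention picks the closest upstream start", {
  # two in-frame starts with no terminator between them and the TGA
  g <- c(chr = "ATGAAAATGAAATGAGGGTAA")
  p <- scanParams(minUpstreamCodons = 0, minOrfLen = 0)
  expect_equal(findCandidateOrf(g, "chr", "+", 12, p)$start_pos, 0L)
  pn <- scanParams(minUpstreamCodons = 0, minOrfLen = 0, startChoice = "nearest")
  expect_equal(findCandidateOrf(g, "chr", "+", 12, pn)$start_pos, 6L)
})

test_that("downstream windows start after the TGA and pad at contig ends", {
  set.seed(10)
  g <- random_dna(800)
  p <- scanParams(windowLen = 300)
  w <- extractDownstreamWindow(c(chr = g), "chr", "+", 100, p)
  expect_equal(w$seq, substr(g, 104, 403))
  expect_equal(w$n_padded, 0L)
  # 10 nt left after the triplet: pad to length with N
  w2 <- extractDownstreamWindow(c(chr = g), "chr", "+", 800 - 13, p)
  expect_equal(nchar(w2$seq), 300L)
  expect_equal(w2$n_padded, 290L)
  expect_true(grepl("N{290}$", w2$seq, perl = TRUE))
  p_nopad <- scanParams(windowLen = 300, padShortWindows = FALSE)
  expect_null(extractDownstreamWindow(c(chr = g), "chr", "+", 800 - 13, p_nopad))
})

test_that("minus-strand windows equal the whole-contig reverse-complement oracle", {
  set.seed(11)
  p <- scanParams(windowLen = 100)
  for (i in 1:25) {
    g <- random_dna(500)
    sites <- enumerateTgaSites(c(chr = g))
    sites <- sites[sites$strand == "-", ]
    if (!nrow(sites)) next
    pos <- sample(sites$pos, 1)
    w <- extractDownstreamWindow(c(chr = g), "chr", "-", pos, p)
    expect_equal(w$seq, brute_window_minus(g, pos, 100))
  }
})

test_that("scanning is deterministic and produces self-consistent ORFs", {
  set.seed(12)
  g <- c(chr = random_dna(4000))
  a <- scanGenome(g)
  b <- scanGenome(g)
  expect_identical(a, b)
  expect_true(nrow(a$orfs) > 0)
  for (i in seq_len(nrow(a$orfs))) {
    o <- a$orfs[i, ]
    expect_equal((o$tga_pos - o$start_pos) %% 3, 0)
    s <- if (o$strand == "+") g[["chr"]] else reverseComplementString(g[["chr"]])
    expect_equal(substr(s, o$tga_pos + 1, o$tga_pos + 3), "TGA")
    expect_true(substr(s, o$start_pos + 1, o$start_pos + 3) %in% c("ATG", "CTG", "GTG"))
    # no terminator strictly between start and TGA
    qs <- seq(o$start_pos + 3, o$tga_pos - 3, by = 3)
    if (length(qs))
      expect_false(any(substring(s, qs + 1, qs + 3) %in% c("TAA", "TAG")))
  }
})
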