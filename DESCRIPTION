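Package: selenoscan
Title: Prediction of Bacterial Selenoprotein Genes by Transformer
    Classification and Homology Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage discovery of selenoprotein genes in bacterial
    genome assemblies. Candidate in-frame TGA codons are enumerated in
    all six reading frames, valid open reading frames are reconstructed
    around them, and the nucleotides immediately downstream of each TGA
    are classified by a k-mer tokenized transformer encoder pretrained
    with a masked-token objective and fine-tuned to separate
    selenocysteine-encoding (Sec) TGA codons from ordinary stop codons.
    Surviving candidates are validated by protein homology: candidates
    are retained when they have a known Sec-containing homolog or at
    least two Cys-containing homologs from different organisms among
    their top hits. Includes corpus construction with
    leakage-controlled train/validation/test splits, greedy
    identity/coverage clustering, seeded simulators for genomes,
    window corpora and homolog databases with known ground truth, and
    GFF3/FASTA report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
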