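---
title: "selenoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{selenoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Selenoproteins incorporate selenocysteine (Sec), the 21st amino acid, at an
in-frame TGA codon — a codon that ordinarily terminates translation. In
bacteria, recoding is directed by a SECIS element, an RNA stem-loop
immediately downstream of the Sec codon, but bacterial SECIS elements are so
heterogeneous that structure-based recognition misses real genes. Standard
gene callers either truncate selenoprotein genes at the Sec TGA or miss them
entirely. `selenoscan` predicts selenoprotein genes in bacterial assemblies
with a two-stage design:

1. **Sequence model stage.** Every TGA triplet in all six reading frames is
   collected; around each, a candidate ORF is reconstructed (start codon ATG,
   CTG or GTG; in-frame TGA; downstream terminator). The window of
   nucleotides immediately downstream of the TGA — the region that carries
   the recoding signal — is tokenized into overlapping k-mers and scored by
   a transformer encoder trained to separate Sec-TGA from stop-TGA contexts.
2. **Homology stage.** Model-positive candidates are translated with `U` at
   the Sec codon and searched against a protein database. A candidate is
   retained only if it has at least one known Sec-containing homolog, or at
   least two of its top ten hits are Cys-containing homologs from different
   organisms — the diagnostic signature of selenoproteins, almost all of
   which have Cys orthologs.

The model stage is a cheap, SECIS-structure-free filter that discards the
overwhelming majority of TGA triplets; the homology stage supplies the
biological evidence.

## Scanner

Coordinates are 0-based, half-open and strand-local throughout the scanner;
conversion to 1-based forward coordinates happens only at GFF3 export.
Ambiguous IUPAC bases never match TGA, and circular replicons are treated as
linear.

Three choices in ORF reconstruction are deliberately configurable because no
single convention is universal:

* **Start choice.** Among upstream in-frame start codons not separated from
  the TGA by a terminator, the farthest one wins (the longest-ORF convention
  of standard gene callers). `startChoice = "nearest"` selects the closest
  instead.
* **Terminator set.** Defaults to `{TAA, TAG}`: a downstream in-frame TGA is
  ambiguous — it could be a second Sec codon — so it does not terminate the
  ORF by default. Adding TGA to `terminatorSet` gives strict scanning.
* **Length floors.** `minUpstreamCodons = 10` and `minOrfLen = 90` nt
  suppress spurious micro-ORFs while keeping short selenoproteins; both can
  be set to 0 to disable filtering.

Windows that run off the contig are padded with `N` (k-mers containing `N`
map to the UNK token) so candidates near contig ends are not lost; padding
is recorded per window.

## Tokenization and the classifier

Windows of length $L \in \{100, 200, 300\}$ nt are tokenized into
overlapping k-mers with stride 1 ($k \in \{3,4,5\}$), giving $L - k + 1$
tokens; the vocabulary holds all $4^k$ k-mers plus PAD, UNK, CLS, SEP and
MASK. Encoded inputs are `[CLS] tokens [SEP]` padded to a fixed
`maxLen = (L - k + 1) + 2`.

The classifier is a pre-LN transformer encoder written for this package
(token + learned positional embeddings, multi-head self-attention, GELU
feed-forward blocks, layer normalization) with two heads: a masked-token
head used for pretraining and a softmax classification head fed by the
first-token (CLS) representation. The numerics (forward, manual backprop,
AdamW) are implemented in C++ (RcppArmadillo) in single precision; the
pre-LN arrangement is used instead of the original post-LN because it
trains stably at the configured constant learning rates without a warmup
schedule.

Training follows the usual two-phase recipe:

* **Pretraining**: masked-token prediction over the unlabeled training
  windows (the training split with labels dropped), masking 15% of k-mer
  tokens (80% MASK / 10% random k-mer / 10% kept).
* **Fine-tuning**: cross-entropy with AdamW; after every epoch the
  validation accuracy is logged, and the returned model is the epoch with
  the highest validation accuracy (earliest on ties).

Two configuration profiles exist. The **paper profile** (the default) is the
full-scale architecture: 768-dim embeddings, 6 encoder layers, 6 heads, 2048
intermediate units, dropout 0.2, pretraining 3 epochs at batch 32,
fine-tuning 10 epochs at batch 128 with learning rate 1e-6. It is intended
for GPU-scale corpora of tens of thousands of windows per class and is not
exercised by the test suite. The **test profile** shrinks the architecture
to 2 layers, 64 dims, 4 heads, 256 intermediate units at learning rate 1e-4
so the whole train-evaluate cycle runs on one CPU in minutes. Because the
learning rate is a constant (no schedule), the number of optimizer steps is
what drives convergence at this scale; the test profile therefore
fine-tunes at batch 16 (pretraining 2 epochs at batch 32, fine-tuning 5
epochs), which gives the small model enough steps to converge on corpora of
a few thousand windows. All randomness — initialization, masking, shuffling,
dropout — flows from the configuration seed, so a training run is
reproducible bit-for-bit on one machine. Inference is deterministic and
batch-size invariant because each sequence is scored independently.

Model selection across window lengths and k-mer sizes is a 9-combination
grid (3 lengths x 3 k); the 300 nt / 3-mer combination — the strongest
performer of the grid at full scale — is the package-wide default.

## Corpus construction

Positive windows are the `L` nt downstream of annotated Sec-TGA codons;
negative windows are the `L` nt downstream of annotated genes that genuinely
end with TGA in organisms that do not use Sec. Splits are family-based to
control leakage: 90% of sequences from 40 randomly chosen selenoprotein
families form the training set; 50% of sequences from 30 further families
form the validation set; all remaining sequences are test candidates, kept
only if their local-alignment identity to every train/val sequence is below
70%. Negatives are randomly partitioned to match each positive split's size.

Greedy clustering (used to de-redundant negative pools) follows the
CD-HIT/MMseqs-style rule: sequences sorted by decreasing length (ties
lexicographic), each joining the first representative at >= 50% identity and
>= 80% bidirectional coverage, else founding a cluster. Identity is defined
as matches over aligned columns (gaps included) of a Smith-Waterman local
alignment (match +1, mismatch -1, gap open 2, extend 1); coverage is the
aligned span over the sequence length, required of both sequences. These
definitions are implemented with `Biostrings::pairwiseAlignment` so the
pipeline has no external binary dependency. The 70% identity cap for the
test set uses a different normalization: local-alignment matches divided by
the shorter sequence length (the CD-HIT convention). Column-normalized
local identity is only meaningful together with a coverage requirement — on
its own any short perfect local match approaches 100% identity, and a
threshold test would exclude everything — so clustering keeps
columns + coverage while the cap uses shorter-length normalization.

## Homology filter

Candidates are translated with bacterial code (table 11), `M` at the
initiator codon and `U` at the candidate TGA. BLOSUM62 has no selenocysteine
row, so for alignment the Sec residue is sent as `C` (maximizing
detectability of Cys homologs; `X` is available via `secSubstitution`), and
the Sec index travels out-of-band. The built-in backend is a Smith-Waterman
local alignment (BLOSUM62, gap open 11/extend 1) with a deterministic
pseudo e-value from the ungapped Karlin-Altschul formula
($E = mn \cdot 2^{-S'}$, $S' = (\lambda S - \ln K)/\ln 2$, $\lambda = 0.267$,
$K = 0.041$); it is *not* calibrated against production aligners and exists
so tests and fixtures run without downloads. Production use should supply
precomputed tabular hits from a real aligner via `hits=`.

Hits are filtered at e-value <= 0.01 and identity >= 20%, sorted by
(e-value, -bitscore, subject id) for determinism, and classified by the
subject residue aligned to the query's Sec position: `U` (or a curated known
selenoprotein whose annotated Sec lands in that column) makes a Sec homolog,
`C` a Cys homolog, anything else — including a gap or a Sec position outside
the aligned span — is "other". The retention rule is exactly: keep on any
Sec homolog anywhere in the filtered list (no rank bound; the criterion text
imposes none), else on >= 2 Cys homologs with pairwise-distinct organism
tags among the top ten hits. Retained candidates are labeled "known" when a
supporting Sec homolog belongs to the curated known-selenoprotein set (best
e-value wins family attribution), otherwise "new".

## Synthetic data

The simulators provide every input with known ground truth:

* **Corpora**: positives carry a 12-nt position-weight-matrix motif at a
  fixed offset (10 nt) after the TGA — a stand-in for the bacterial SECIS
  element, which sits immediately downstream of the Sec codon. The PWM puts
  `strength + (1 - strength) * bg` mass on the consensus base, so strength 0
  is exactly background and strength 1 is deterministic. Positives have
  family structure (prototype + 10% per-position mutation) so clustering and
  identity-capped splits have structure to find; negatives are i.i.d.
  background at the configured GC content.
* **Genomes**: planted selenoprotein genes are valid ORFs (ATG start,
  in-frame TGA, motif downstream, TAA terminator) preceded by an in-frame
  TAA so the reconstructed ORF matches the planted coordinates exactly;
  decoys genuinely end with stop-TGA and carry no motif. Genes are placed
  non-overlapping on both strands with at least 350 nt clearance.
* **Databases**: each planted selenoprotein family gets >= 2 Cys-variant
  homologs (U -> C, then 5-15% substitutions) under distinct organism tags,
  optionally a Sec-containing "known" entry, plus unrelated random proteins;
  decoys get no homologs.

The motif is a PWM, not a folded stem-loop: the classifier contract only
needs a learnable downstream signal, and the model itself is deliberately
structure-agnostic. Consequently, passing tests demonstrate that the
two-stage architecture, training loop and filter behave correctly and can
learn a downstream recoding signal — they do not demonstrate recovery of
real SECIS thermodynamics, phylogenetic realism of homolog sets, or the
performance level reported for the full-scale corpus. The motif consensus is
T-free so it can never introduce an in-frame stop codon into a planted gene.

## Reference study conditions and problem sizes

The package's reference conditions, used by the test suite and the
acceptance script, are fixed at: corpora of 2,000 + 2,000 windows of 300 nt
at motif strength 0.8 (70/15/15 train/val/test), the 3-mer vocabulary, the
test-profile transformer, and a 100-kb genome carrying 10 planted
selenoprotein genes (with fixture homologs) and 50 stop-TGA decoys. Property
checks that are scale-free (e.g. AUROC monotone in motif strength) run at
smaller sizes (windows of 100 nt, corpora of a few hundred windows,
1-layer/32-dim models). These sizes are the package's own choice of a
desk-scale experimental design; the full-scale conditions (tens of
thousands of windows, 768-dim model) are retained as the default "paper"
profile.

## Numerical choices and degenerate inputs

* Metrics: precision is NA when nothing is predicted positive; F1 is 0 when
  precision + recall is 0; AUROC uses midranks (ties count half) and is
  undefined (an error) for one-class labels.
* Classification threshold 0.5 unless overridden; the same threshold gates
  the pipeline's filter stage.
* Softmax and layer-norm use the usual max-subtraction / epsilon (1e-5)
  stabilizations; cross-entropy clips probabilities at 1e-12.
* AdamW: beta = (0.9, 0.999), eps = 1e-8, decoupled weight decay 0.01
  applied to weight matrices only (not biases or layer-norm parameters).
* Empty genomes, zero-TGA contigs and empty hit lists all produce empty,
  well-formed results rather than errors; empty corpora and single-class
  label sets are errors.
* Hit-order ties are broken by bitscore then subject id so reports are
  byte-stable.

## Known limitations

* The built-in aligner's e-values are uncalibrated; thresholds tuned for
  DIAMOND/BLAST semantics are only approximately comparable.
* The pipeline scans TGA-anchored ORFs only; it is not a general gene
  caller, does not resolve overlapping gene models, and treats every contig
  as linear.
* No SECIS secondary-structure validation is performed on new candidates;
  that remains a manual downstream step.
* The full-scale ("paper") profile configuration is provided, but training
  it to production quality requires corpus and compute scale outside this
  package's test envelope.
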