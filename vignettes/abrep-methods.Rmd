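---
title: "Models and methods behind abrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind abrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrep)
```

# Scope

`abrep` turns raw B-cell receptor (BCR) repertoire sequencing reads into a
curated set of unique, annotated V(D)J transcripts and computes three kinds of
repertoire-level summaries on top of them: clonotypes with gene-specific
substitution profiles (GSSP) and mutation-rarity scores, gene-specific
N-glycosylation profiles (GSNP), and signature-prevalence estimates with
rarefaction.  Everything is testable offline because the package ships a
generative simulator whose ground truth records every read-to-cell mapping.

This vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic data can and cannot show.

# Curation model

Raw reads are distorted by three processes the curation stage must undo:
multiple mRNA molecules per cell, PCR duplication with per-base error, and
sequencing miscalls.  Two paths are provided, mirroring how libraries are
actually prepared:

* **UMI path** (`umi_consensus()`).  Reads are grouped by identical UMI.
  Because PCR crossover and UMI collisions can put molecules from different
  cells under one tag, each group is re-clustered at 97% identity before a
  column-wise majority consensus is taken per subcluster (star alignment to
  the most abundant member; ties resolve to that member's base, majority-gap
  columns are dropped).  Exact duplicates among consensus sequences collapse
  (multiple mRNAs of one cell), and *singletons* — consensus sequences with
  neither UMI duplicates nor consensus duplicates — are removed as
  unverifiable.
* **Cluster path** (`cluster_dedup_no_umi()`).  Exact duplicates are counted
  first, then greedy centroid clustering at 99% identity; each cluster emits
  its highest-depth member with the cluster's total read count, and clusters
  with fewer than 2 reads are dropped.

Repertoires with fewer than 1,700 unique transcripts are excluded from
profile building; the quality filters upstream drop merged transcripts
shorter than 300 nt or with more than 20 expected miscalls
(`sum(10^(-Q/10))` over the Phred scores).

## Sequence identity and clustering

Both clustering stages use `pairwise_identity()`: `1 - d / max(len)` where
`d` is the unit-cost Levenshtein distance (computed in C via
`utils::adist`).  For equal-length, substitution-only pairs — the regime
deduplication operates in — this equals matching columns over aligned
columns of the optimal global alignment.  We deliberately do not use
free-end-gap score maximisation for the *identity* statistic: a score-maximal
ends-free alignment of `ACGT` against `ACGA` drops the terminal mismatch and
would report identity 1.0 where 0.75 is the intended answer.

`greedy_cluster()` processes records in a fully deterministic order
(abundance descending, then longer sequence, then lexicographic) and assigns
each record to the *first* centroid at or above the threshold, else founds a
new cluster.  Two screens keep this fast without changing results: a length
window (`|la - lb| > (1-t) * max` rules identity `>= t` out) and a pigeonhole
block screen (identity `>= t` bounds the edit distance by `L(1-t)/t`, so at
least one of `d+1` contiguous blocks of the record must occur verbatim in any
joinable centroid).  Both are provable exclusions, so the greedy result is
identical to the brute-force scan — a property the test suite checks against
an independent re-implementation.

# Annotation model

Germline V/(D)/J assignment uses local alignment (Smith–Waterman via
`Biostrings::pairwiseAlignment`) with nucleotide-BLAST-like scoring: match
+2, mismatch −3, gap open 5, gap extend 2.  Significance is summarised by
`evalue_like = K·m·n·exp(−λS)` with K = 0.41, λ = 0.625; isotype calls
(CH1 database search on the 3′ terminus) require `evalue_like ≤ 1e-6`.
Ties between equal-scoring V alleles break by identity and then by allele
name, so runs are reproducible.  The D segment is only called when the best
D alignment contains at least 5 contiguous matching nucleotides, which
prevents spurious D calls on short junctions.

The CDR3 is delimited by the conserved 2nd Cys of the V segment (IMGT
position 104, located through the germline's gapped coordinates) and the
first W of WGXG (heavy) or F of FGXG (light) in the V reading frame within
the J span; the junction between them (IMGT 105–117 convention) must be a
codon multiple, and the observed anchor codon must still encode Cys.
Transcripts are productive only when both anchors are intact, the V
alignment carries no net out-of-frame indel, and no stop codon occurs
through the J region.

Hypermutation (`shm_nt_pct`) is 100 × mismatched / aligned V columns with N
bases excluded from both counts.  Position numbering is IMGT-native (the
gapped germline columns *are* the IMGT coordinates; the CDR3 is filled
symmetrically from 105 up and 117 down with 111.x/112.x insertion codes
beyond 13 residues).  Kabat and Chothia numbering are produced by composing
the IMGT map with a static translation table shipped for the toy reference
(`default_numbering_table()`, user-replaceable); positions missing from the
table are reported unmapped rather than guessed.  Full HMM-based numbering
of arbitrary human germlines is out of scope.

# Profiles and rarity

Clonotypes group transcripts by gene-level V and J call and CDR3 length,
then cluster CDR3 nucleotide sequences at 90% identity; the clone
representative is the highest-depth member.  A GSSP pools representatives of
one V gene across repertoires and tabulates, at every IMGT position, the
frequency of each non-germline residue.  Two normalisations are provided
because the rarity threshold semantics read most naturally as unconditional
frequency: `per_observed` (default; denominator = representatives observing
the position, unmutated ones included) and `per_mutated` (denominator =
representatives mutated at the position; frequencies then sum to 1 where any
mutation was seen).  Results always label their mode.  Profiles with fewer
than 100 clones are withheld as under-supported.

Mutation rarity is `(1 − frequency) × 100` per cent, computed exactly, with
substitutions below 0.5% frequency flagged rare.  GSSPs are keyed by gene,
not allele; the assigned allele's residues serve as each transcript's
germline baseline, so allele polymorphisms are not mistaken for
hypermutation.

GSNPs count N-glycosylation sequons (N-X-S/T with X ≠ P) that hypermutation
introduced: transcripts with SHM > 1% are eligible, sequons present at the
homologous IMGT positions of the germline V are excluded, and a sequon is
counted only when all three residues are numbered.  The sequon rule is
sequence-based; relative to a structure-aware neural-network predictor the
frequencies are an upper bound, which is the documented trade-off for having
a fully reproducible rule.  Denominators count transcripts (not donors).

# Prevalence and rarefaction

Signature queries come in three modes: anchored CDR3 motifs in the
dash-separated grammar used in repertoire figure legends (`X` = any of the
20 amino acids, `[...]` = residue class), numbered-position constraints
(failing on unobserved positions), and similarity search (local alignment at
`evalue_like < 1e-6`).  A repertoire's signature frequency divides matched
transcripts by the unique transcripts of the query's germline gene; the
denominator is configurable (`"gene"` vs `"all"`) because gene-origin
signatures only make sense against the whole repertoire.  A zero denominator
reports an absent frequency, never 0.  Paired heavy/light prevalence under
random pairing is the product of two whole-repertoire frequencies, reported
per million B cells to two significant figures.

Rarefaction draws, for each sampling size *i*, `n_repeats = 20` subsets of
*i* repertoires without replacement (independently across repeats, one
seeded generator), takes the mean per-repertoire frequency of each repeat,
and reports `CV_i = sd / mean` over the repeat means with the sample (n−1)
standard deviation.  `exhaustive = TRUE` enumerates all subsets instead,
which is what makes small-panel results exactly checkable against explicit
enumeration.

# The simulator and what it does (not) show

`simulate_repertoire()` draws, per cell: a V/(D)/J recombination with
geometric N-regions (mean 4 nt per side, junction padded to keep the J
anchor in frame, junctions resampled until the CDR3 is stop-free and its
first anchor-motif occurrence is the true anchor); point hypermutation at
`shm_rate` (default 0.02) with a `hotspot_multiplier` (default 3) inside
WRC/GYW motifs; `min + Poisson(mean − min)` mRNA molecules (default 1 + 1)
and PCR copies per molecule; per-base PCR error (default 1e-4 per copy);
UMIs with a configurable collision rate; and clipped-normal Phred scores
(default Q38 ± 3) with miscalls injected at exactly `10^(-Q/10)` so the
expected-error filter is exercised honestly.  All draws come from one seeded
stream; identical configs are byte-identical.  The min+Poisson copy-number
parameterisation was chosen so exact-count scenarios ("every molecule seen
in 2 copies") are expressible as `min = mean` configs.

For the curation-recovery checks the generator uses 1,000 cells with five
PCR copies per molecule at PCR error 1e-3.  Five (an odd count ≥ 3) makes
the per-column majority strict, so single-copy errors can never tie the
vote; at three copies, two reads sharing one coincidental error would
corrupt roughly one consensus per two thousand molecules, making exact
recovery a coin flip on the seed rather than a property of the method.  On
the cluster path, a cell none of whose duplicates is error-free necessarily
yields a representative one or two bases off the true transcript — the
highest-depth rule cannot do better — so that path is assessed by recall
plus *neighborhood* precision (every emitted unique within the 0.99
clustering identity of a true transcript).

The simulator deliberately omits: insertion/deletion hypermutation (the
annotation pipeline excludes frameshifted transcripts, so substitutions
exercise every stage), chimeric PCR products, position-dependent quality
decay, primer/adapter artefacts, and paired heavy–light single-cell
structure.  Passing tests therefore demonstrate the correctness of the
implemented rules under substitution-type noise, not robustness to every
artefact of real libraries.

# Problem sizes and numerical choices

The test and acceptance workloads use 1,000-cell repertoires (≈10,000
reads) for curation recovery, 1,000 clone representatives for profile
recovery, 10,000 random 200-mers for the sequon oracle, 200 random trials
for the clustering oracle, and 25 independent 35-repertoire panels for the
rarefaction trend — sizes at which every stochastic check has comfortable
margin (a planted 10% frequency at n = 1,000 has binomial SE ≈ 0.0095)
while the whole suite stays interactive.

Degenerate inputs are handled explicitly: empty germline files load as empty
sets with a warning; duplicate allele names are configuration errors;
FASTQ structure is validated before parsing (the C parser does not check
sequence/quality agreement); records without qualities skip the
expected-error filter; zero-denominator frequencies are absent, not zero;
and `compare_gssp()` returns `NA` when profiles share no covered cells.

# Known limitations

* Kabat/Chothia numbering is table-driven and shipped only for the bundled
  toy reference; users must supply their own table for real germline sets.
* The non-UMI path's representative choice is depth-based; it cannot correct
  a cell whose every read is erroneous (see above).
* `pairing_frequency()` assumes independent heavy/light pairing and
  whole-repertoire frequencies on both sides; gene-conditional inputs would
  need the gene-usage factors multiplied in first.
* GSNP frequencies are sequon-rule upper bounds, not accessibility-filtered
  predictions.
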