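# abrep — antibody repertoire curation, substitution profiles and signature prevalence

`abrep` is an R toolkit for B-cell receptor (BCR / antibody) repertoire
sequencing.  It takes raw Rep-seq reads and produces a curated set of unique,
annotated V(D)J transcripts, then computes the repertoire-level summaries an
immunogenetics analyst actually asks for:

* **Curation** — read-pair merging, quality filtering (expected miscalls
  `Σ 10^(-Q/10)` ≤ 20, length ≥ 300 nt), and deduplication via either UMI
  consensus (group by UMI → 97%-identity subclusters → majority consensus →
  singleton removal) or USEARCH-style greedy clustering at 99% identity with
  highest-depth representatives and removal of size-1 clusters.  Repertoires
  with < 1,700 unique transcripts are excluded.
* **Annotation** — germline V/(D)/J assignment by local alignment against an
  IMGT-gapped reference, CDR3 extraction between the conserved 2nd Cys
  (IMGT 104) and the WGXG/FGXG J anchor (IMGT 118), isotype calling from the
  CH1 region (E-value ≤ 1e-6), frameshift/stop productivity checks, somatic
  hypermutation (SHM) quantification, and IMGT / Kabat / Chothia position
  numbering.
* **Clonotypes & GSSPs** — clones share gene-level V, J, CDR3 length and
  ≥ 90% CDR3 identity; gene-specific substitution profiles tabulate per-IMGT
  position amino-acid substitution frequencies across ≥ 100 clone
  representatives, and each observed mutation is scored as
  `Rarity = (1 − frequency) × 100%`, with frequency < 0.5% flagged rare.
* **GSNPs** — N-glycosylation sequons (N-X-S/T, X ≠ P) introduced by SHM
  (> 1%), excluding germline-encoded sites.
* **Prevalence & rarefaction** — CDR3-motif, numbered-position and
  sequence-similarity signature search; per-repertoire frequencies against a
  same-gene or whole-repertoire denominator; paired heavy/light prevalence
  under random pairing; and rarefaction curves with the coefficient of
  variation `CV_i = sd(repeat means) / mean(repeat means)` over N = 20
  subsamples per size.
* **Simulator** — a ground-truthed generator (V(D)J recombination,
  hotspot-biased SHM in WRC/GYW motifs, mRNA copies, PCR duplication with
  errors, Phred-consistent miscalls, UMIs with collisions) so every stage is
  testable without any external data.

## Worked example

Simulate a UMI-tagged repertoire of 200 cells, curate it, and annotate the
first 50 unique transcripts:

```r
library(abrep)

cfg <- sim_config(seed = 42, n_cells = 200, umi_length = 12,
                  pcr_duplicates_mean = 5, pcr_duplicates_min = 5)
sim <- simulate_repertoire(cfg)        # 1,880 reads
cur <- umi_consensus(sim$records)      # 200 unique == 200 true transcripts
ann <- annotate_repertoire(cur$unique[1:50, ], sim$germline)
head(ann[, c("read_id", "v_call", "j_call", "isotype", "cdr3_aa",
             "shm_nt_pct", "productive")], 3)
#>      read_id     v_call     j_call isotype           cdr3_aa shm_nt_pct productive
#> 1 uniq000001 IGHV-T4*01 IGHJ-T2*01     IgM  WHSSSWYGGYYYGMDV  3.1250000      FALSE
#> 2 uniq000002 IGHV-T3*01 IGHJ-T1*01     IgA       GLYSSSWYVDY  0.3472222      FALSE
#> 3 uniq000003 IGHV-T2*01 IGHJ-T2*01     IgM ILRFLEWFIKYYYGMDV  2.4305556       TRUE
```

Every V call matches the simulator's ground truth; the mean SHM here is
2.67% (the configured 2% base rate plus the 3× hotspot bias), and about half
the cells are non-productive because the simulator mutates without selection
— exactly the transcripts the productivity filter exists to remove.

Paired-chain arithmetic and rarefaction:

```r
pairing_frequency(0.027, 0.00005)   # heavy 2.7% x light 0.005%
#> [1] 1.4                           # per million B cells

f <- c(0.031, 0.012, 0.047, 0.025, 0.002, 0.038)  # per-repertoire frequencies
rarefaction_cv(f, sizes = c(2, 4, 6), n_repeats = 20, seed = 7)
#>   size n_repeats  mean_freq        cv
#> 1    2        20 0.02637500 0.3510074
#> 2    4        20 0.02413750 0.1716245
#> 3    6        20 0.02583333 0.0000000
```

`pairing_frequency(0.027, 0.00005)` is the random-pairing estimate for an
HIV-1 VRC01-class antibody: a heavy-chain signature seen at 2.7% and a light
chain at 0.005% co-occur in ~1.4 cells per million.  The CV falls to zero at
the full panel size because every subsample is then the whole panel.

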