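Package: abrep
Title: Antibody Repertoire Curation, Substitution Profiles, and Signature Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for B-cell receptor (BCR) repertoire sequencing analysis:
    curation of raw antibody-repertoire reads into unique annotated V(D)J
    transcripts (read merging, quality filtering, UMI consensus and
    cluster-based deduplication), germline V/(D)/J assignment and CDR3
    junction identification against an IMGT-gapped reference, isotype calling,
    somatic hypermutation quantification, antibody position numbering (IMGT,
    with table-driven Kabat/Chothia), clonotype clustering, gene-specific
    substitution profiles (GSSP) with mutation-rarity scoring, gene-specific
    N-glycosylation profiles (GSNP), and signature-prevalence search with
    rarefaction analysis.  Includes a synthetic repertoire simulator with
    full ground truth (V(D)J recombination, hotspot-biased point hypermutation,
    mRNA copies, PCR duplication with errors, Phred qualities, UMIs with
    collisions) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
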