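Package: phylocrate
Title: Provenance-Explicit Multilocus Phylogenomics Projects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-container environment for multilocus phylogenomic
    experiments. A project object holds loci, sequence records, alignments,
    trees, supermatrices and per-locus statistics together with an append-only
    provenance ledger, so that every data object is traceable to the operation
    and parameters that produced it. Supports GenBank and FASTA harvesting with
    alias-folded locus assignment, record and locus filtering, per-column
    Shannon entropy and related alignment statistics, parameter-gradient
    supermatrix construction by slicing and sliding windows, gap-threshold
    trimming, neighbor-joining trees with external-tool adapters,
    Robinson-Foulds and branch-score tree comparison, and a reproducibility
    layer of content-addressed checkpoints, human-readable reports and
    self-contained archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
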