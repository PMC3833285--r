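Package: midsat
Title: Discovery of Medium-Sized Tandem Repeats by In Silico Restriction
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to discover and characterise medium-sized (40-500 bp)
    tandem repeats (satellite monomers) in draft genome assemblies by
    combining in silico restriction digestion with direct tandem-array
    scanning.  Digests a genome at the recognition sites of a panel of
    restriction enzymes, builds fragment-length distribution diagrams,
    calls sharp peaks, predicts which peaks would be visible as bands on
    a gel, and intersects peak lengths across enzymes to nominate tandem
    repeat unit lengths.  A k-mer seeded scanner detects head-to-tail
    arrays, produces a per-period census of repeat units and clusters,
    and assembles IUPAC consensus monomers on which restriction sites
    are mapped under a circular-monomer model.  A greedy tiling
    annotator decomposes repeat-cluster loci into full-length,
    5'-truncated, and short-fragment copies of a consensus.  A seeded
    synthetic-genome generator with planted ground truth makes every
    stage testable without external data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
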