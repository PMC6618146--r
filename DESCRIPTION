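Package: ferro
Title: Gene-Centric Metatranscriptomics of Iron-Related Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-centric metatranscriptome profiling of iron-related
    metabolic pathways in marine prokaryotic communities: curation and IO of
    pathway-tagged protein reference databases with taxonomy lineages and KEGG
    annotations, best-hit read recruitment from translated-alignment tabular
    output (plus a built-in desk-scale six-frame translated search),
    taxon-resolved transcript count aggregation and relative-contribution
    profiling, a 16S copy-number-corrected cell census anchored on CARD-FISH
    total counts, and a qPCR-anchored normalization that converts read counts
    into absolute transcripts per litre and per-cell expression with
    between-station log-ratios. A seeded synthetic-community generator
    produces ground-truth communities and every pipeline input so the whole
    chain can be exercised and validated by parameter recovery without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
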