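Package: mapweave
Title: Genetic-Map-Guided Genome Assembly Improvement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to rebuild, at desk scale, a genome-improvement workflow
    that combines a recombinant inbred line (RIL) genetic map with long-read
    gap filling. Includes a synthetic-data module (multi-chromosome genomes,
    gapped draft scaffolds, F8 RIL populations under the Haldane model with
    GBS-like missingness, error-bearing long reads), GBS marker reduction,
    LOD-based linkage grouping with Kosambi and Haldane map distances,
    genetic-map anchoring of scaffolds into pseudomolecules joined by 100-N
    gaps, k-mer-anchored gap filling with a split/reconnect reconciliation
    between the base and the map-integrated assembly, GFF3 annotation
    liftover with pseudogene classification, and assembly statistics
    (N50/L50, gap registries, AGP export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
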