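Package: ssga
Title: Hybrid Genome Assembly with a Synthetic Scaffolding Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Core algorithms for hybrid de novo genome assembly from
    short-read contigs and error-prone long reads, without all-versus-all
    long-read overlap computation. Synthetic mate pairs are extracted from
    long reads at a spectrum of insert sizes and pseudo-aligned to the
    contigs with a minimizer index and co-linear chaining; the resulting
    synthetic scaffolding graph (contig-end vertices, bundled long-read
    labeled mate edges) is transitively reduced along long-read-coherent
    paths, covered by a maximum-weight matching to order and orient the
    contigs, validated by long-read physical coverage, gap-filled by
    windowed partial-order-alignment consensus and polished with leftover
    contigs. Includes a seeded simulator for genomes with repeat structure,
    error-bearing long reads, short read pairs and draft contigs (with
    optional induced chimeras) so that every stage can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
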