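Package: mitoDRRL
Title: Double-Replication Random-Loss Models for Mitochondrial Gene-Order
    Rearrangement
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying genome-scale gene-order rearrangement in
    vertebrate mitochondrial genomes under duplication-and-random-loss
    models. Provides circular gene-order data structures with the canonical
    vertebrate 37-gene + control-region order, forward simulators for
    control-region duplication/translocation, double replication between two
    replication origins, and random loss of duplicated gene copies (DRRL), as
    well as classic tandem duplication random loss (TDRL); an inference
    engine that decides one-step derivability of an observed order via
    two-increasing-run decomposition of the rearranged block and enumerates
    all explanations with remnant support; annotation-table statistics for
    circular mitogenomes (sizes, intergenic spacers, overlaps); seeded
    synthetic-case generators with ground truth; and the packaged annotation
    of the Samariscus latus mitogenome together with its six-stage
    rearrangement reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
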