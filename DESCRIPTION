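Package: seedcoat
Title: Three-Locus Epistatic Modeling of Cowpea Seed-Coat Pattern
Version: 0.1.0
Authors@R:
    person("UCR", "Cowpea Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the three-locus epistatic control of seed-coat pattern in
    cowpea (Vigna unguiculata) by the Color Factor (C), Watson (W) and
    Holstein (H) loci. Provides exact (rational-arithmetic) segregation-ratio
    prediction for F2, recombinant inbred line (RIL) and eight-parent MAGIC
    designs, chi-square goodness of fit of observed phenotype class counts, a
    seeded forward crossing simulator under the Haldane map function, an
    algorithmic bulked-segregant zygosity scan with minimal-haplotype-block
    intersection, a simplified single-marker association scan with
    permutation thresholds, and a synthetic-data generator that builds every
    fixture needed to exercise the above without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
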