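Package: melmap
Title: Pool-Scan, Linkage and Identical-by-Descent Mapping of a Dominant
    Plumage-Pattern Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale re-usable implementation of a classic forward-genetics
    inference chain for a dominant, incompletely penetrant Mendelian locus:
    pooled allele-frequency genome scans (absRAFdif and windowed Z-scored
    F_ST), two-round back-cross linkage refinement with recombinant
    classification and penetrance estimation, identical-by-descent (IBD)
    shared-haplotype detection among carrier panels, a two-stage
    candidate-variant concordance filter, and qPCR/allelic-imbalance
    expression follow-up (delta-delta-Ct and genomic-DNA-normalised peak
    ratios). Includes a seeded synthetic-data generator that emulates the
    back-cross, pool-seq read sampling, carrier breed panels with a planted
    IBD segment and decoy variants, and two-transcript cis-regulatory
    expression data, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
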