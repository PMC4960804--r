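Package: senescape
Title: Chromatin Landscape Analysis of Senescence-Associated Heterochromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ChIP-seq interval and signal data for
    senescence-associated heterochromatin studies. Provides genome-aware
    interval algebra and BED input/output, fragment-extended reads-per-million
    window signal with control subtraction, permutation-based
    observed-to-expected overlap enrichment with gap-aware matched
    randomization, scaled composite (metadomain and metagene) profiles,
    telomeric-repeat read quantification, transposable-element
    evolutionary-order enrichment, expression-quartile integration, and a
    synthetic-data generator that plants known enrichment structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
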