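Package: ervtools
Title: Association and Expression Analysis of Endogenous Retroviral Elements
Version: 0.1.0
Authors@R:
    person("ervtools", "developers", email = "ervtools@example.org",
           role = c("aut", "cre"))
Description: Tools for linking endogenous retrovirus (ERV) loci to
    cell-type-specific chromatin and transcription-factor ChIP-seq peaks,
    and for quantifying repeat-element expression from RNA-seq alignments.
    Implements a precision/sensitivity F-beta association statistic against
    random control loci with log-space Fisher exact significance, window-sweep
    association profiles with hierarchical clustering of cell types,
    probabilistic reassignment of multimapping reads based on unique coverage
    of flanking context regions, RPKM quantification with a correction that
    separates element-specific from read-through (unspecific) transcription,
    transcription-factor proximity and ordering analyses at proviral 5' LTRs,
    polar chromosome-projection ("mandala") visualisation, and a fully
    deterministic synthetic-data generator so the complete pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
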