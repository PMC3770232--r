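Package: peakreg
Title: Annotation and Regulatory Integration of Transcription Factor
    Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of transcription-factor binding sites
    called from tiling-microarray or ChIP experiments: signed
    distance-to-TSS mapping with seeded random null site sets,
    classification against transcribed regions and regulatory-element
    tracks (DNase hypersensitive sites, predicted enhancers, insulators)
    with exact enrichment tests, degenerate IUPAC consensus-motif
    scanning with width-paired GC-reported random backgrounds,
    promoter-array capture prediction for platform-specific windows, and
    integration of binding with knockdown and overexpression expression
    contrasts, including regulated-fraction analyses by distance bin,
    site count and gene position.  A fully seeded synthetic-data
    generator with a ground-truth manifest makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
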