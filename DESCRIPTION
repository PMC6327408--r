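Package: pifminer
Title: Mining and Classification of PIF-Like DNA Transposons with TIR and
    TSD Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies PIF/Harbinger-like class-II DNA transposons in genome
    assemblies by degenerate terminal-inverted-repeat (TIR) motif scanning,
    de novo inverted-repeat discovery, TIR pairing with target-site
    duplication (TSD) validation, and six-frame translated alignment against
    ORF1/transposase references. Elements are assigned structural classes
    (autonomous, defective, MITE-like), grouped into families with the
    80-80-80 rule, and intersected with gene models to report exon, intron
    and intergenic insertion contexts. Includes an in-silico transposon
    display simulator (restriction digest, adapter ligation, selective
    amplification, differential band calling) and a synthetic-genome
    generator that plants element copies with known coordinates for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
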