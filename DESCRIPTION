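Package: pbsite
Title: Transgene Integration-Site Discovery from Soft-Clipped Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of PiggyBac transposon integration
    sites from whole-genome paired-end sequencing, built around soft-clipped
    split-read junction evidence: a seeded soft-clipping read aligner with
    coordinate duplicate removal, junction clustering with TTAA target-site
    duplication detection, and hybrid-reference validation. Includes a
    synthetic-data module (toy genomes, transgene insertions with target-site
    duplication, paired-end read simulation with a Phred quality model,
    Mendelian offspring and qPCR Ct panels), the read quality-control filters
    used for such data, a Mendelian transmission model of hemizygous
    transgene loci across backcross generations, and comparative-CT
    (2^-ddCt) relative-expression and summary-statistics t-test utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    methods,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
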