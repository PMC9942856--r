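Package: ieskit
Title: Characterization of Internal Eliminated Sequences, Terminal
    Repeats, MITE Families and Developmental Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream characterization of internal eliminated
    sequences (IESs) in ciliate germline genomes, modelled on the
    Blepharisma stoltei IES landscape. Provides filtering of IES
    predictions, detection of terminal direct repeats (pointers) with
    left-most normalization of floating excision junctions, exact
    ungapped terminal inverted repeat (TIR) scanning, a geometric null
    model for repeat-length enrichment, IES length-peak calling with
    half-height size classes and periodicity estimation, MDS-IES
    junction base-count matrices, hybrid (somatic + IES) assembly
    construction with coordinate liftover, mobile-IES (MITE/MITIES)
    calling against family TIR/TSD signatures, tandem-repeat period
    detection, developmental small-RNA feature counting with RPKM and
    positional base-bias summaries, and a synthetic-data generator
    that plants all of these structures with known ground truth.
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
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
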