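Package: nifHeval
Title: In Silico Evaluation of Degenerate PCR Primers for the nifH Marker Gene
Version: 1.0.0
Authors@R:
    person("nifHeval", "Developers", email = "nifheval@example.org",
           role = c("aut", "cre"))
Description: Tools for in silico evaluation of degenerate PCR primers
    against aligned marker-gene databases, built around the nifH gene of
    nitrogenase reductase, the standard marker for nitrogen-fixing Bacteria
    and Archaea. Ships a curated registry of published universal and
    group-specific nifH primers and primer pairs, and provides IUPAC-aware
    mismatch-tolerant primer scanning, sequence-depth-normalised coverage
    statistics stratified by phylogenetic group and environment, primer-pair
    amplicon prediction, degeneracy and nearest-neighbor melting-temperature
    characterisation, and a manifest-driven synthetic aligned-database
    generator that provides exact ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
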