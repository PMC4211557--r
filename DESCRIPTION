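Package: tcemrep
Title: T-Cell Exposed Motif Analysis of Immunoglobulin Repertoires
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extraction and frequency analysis of T-cell exposed motifs (TCEM)
    and groove-exposed motifs (GEM) from immunoglobulin heavy-chain variable
    regions and arbitrary protein sets. Enumerates 9-mer and 15-mer peptide
    windows, extracts the six non-contiguous motif registers, classifies motif
    re-use into reciprocal base-2 logarithmic frequency classes, attributes
    motifs to germline versus somatic-hypermutation origin, maps overlapping
    recognition frames (TCEM, GEM, cathepsin cleavage octamers), and scores
    MHC presentation through a pluggable affinity/cleavage predictor layer
    with ensemble aggregation and within-protein Johnson Sb standardization.
    Includes a ground-truth somatic-hypermutation repertoire simulator and a
    file-based analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
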