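Package: tyland
Title: Ty1 Retrotransposon Landscapes in Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Curation of raw repeat-annotation hits into structurally
    classified Ty elements (full-length, truncated, solo LTR), strand-aware
    sequence extraction and BED12 interchange, Kimura 2-parameter divergence
    in sliding windows, distance-based clustering (NJ/BIONJ) with bootstrap
    support, classification of Ty1 subfamilies (canonical vs Ty1') and
    detection of recombination breakpoints in mosaic elements, and the
    copy-number-control statistics linking genomic Ty1 gag content to
    mobility phenotypes. Includes a synthetic-genome generator that plants
    Ty elements with known ground truth to validate every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
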