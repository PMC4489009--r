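Package: gliadinR
Title: Annotation and Expression Analysis of Wheat Gliadin Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for annotating prolamin seed-storage-protein (gliadin)
    gene families in diploid wheat: open-reading-frame and pseudogene
    classification with mutational-origin calls for internal stop codons,
    type-specific structural domain segmentation (alpha, gamma and omega
    gliadins), celiac-disease epitope and repeat-motif scanning, cysteine
    skeleton profiling, theoretical molecular weight and isoelectric point,
    RPKM-based expression classification across grain development, in-silico
    chymotryptic digestion with two-dimensional-electrophoresis spot
    assignment, and a ground-truthed synthetic gliadin family generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    tibble,
    dplyr,
    readr,
    stringr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
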