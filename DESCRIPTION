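Package: viroscape
Title: Host Typing, Fold Conservation and Genomic-Context Mining for Viral Protein Structure Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Downstream analysis of large viral protein structure catalogues:
    assignment of host domains (bacteria, archaea, eukaryota) to viral proteins
    via a virus-host mapping table, classification of sequence- and
    structure-level protein clusters as monohost or heterohost under a
    minority-count rule, comparison of sequence and structure clusterings,
    confidence triage of predicted monomer and homodimer models (pLDDT, ipTM),
    TM-score-weighted inference of oligomeric states from structure-search
    hits, best-hit selection and threshold filtering against defense and
    antidefense model libraries, and mining of conserved bicistronic gene
    patterns with toxin-antitoxin characteristics from genomic-context tables.
    Includes seeded synthetic-data generators with planted ground truth for
    every input table the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    yaml,
    bio3d,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
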