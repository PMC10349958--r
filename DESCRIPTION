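Package: abagqc
Title: Quality Assessment of Predicted Antibody-Antigen Complex Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates predicted antibody-antigen complex models against
    experimentally determined reference structures. Implements DockQ-style
    complex accuracy scoring (fnat, interface RMSD, ligand RMSD, CAPRI
    accuracy classes), interface-pLDDT confidence aggregation, CDR loop
    RMSD under AHo scheme numbering, interface glycan detection, antigen
    TM-score, effective MSA depth by greedy identity clustering, benchmark
    non-redundancy curation rules, and top-N success-rate / ROC-AUC
    aggregation. Ships a synthetic complex and decoy generator with planted
    ground truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
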