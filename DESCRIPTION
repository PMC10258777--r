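Package: glycoMHC
Title: Glyco-Immunopeptidomics: Sequon-Aware Glycopeptide Search with
    Group-Specific FDR and HLA Class II Motif Deconvolution
Version: 0.1.0
Authors@R:
    person("glycoMHC", "Developers", email = "glycomhc@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for the analysis of N-glycosylated
    MHC-associated peptides from non-enriched immunopeptidome data.
    Implements a nonspecific (non-enzymatic) peptide index with reversed
    decoys and sequon parity, oxonium-ion spectrum triage, a mass-offset
    glycopeptide search with hyperscore ranking, layered target-decoy FDR
    control with separate score thresholds for glycosylated and
    non-glycosylated PSM groups, glycan composition assignment with
    decoy-glycan q-values, and HLA class II binding-core deconvolution
    (PWM mixture EM) with core-relative glycosite characterization.
    Ground-truth synthetic generators make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
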