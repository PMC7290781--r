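Package: venomtx
Title: Toxin Mining, Naming and Proteome Mapping for Venom-Gland
    Proteo-Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for annotating venom-gland transcriptome
    assemblies and reconciling them with shotgun proteomic evidence. Provides
    six-frame translation and ORF extraction, TPM abundance computation,
    keyword-driven toxin mining of homology-annotation tables, toxin-precursor
    parsing with mass-based inference of C-terminal amidation-signal
    processing, cysteine-scaffold extraction with conotoxin-framework and
    inhibitor-cystine-knot classification, a rational toxin-nomenclature
    engine for peptide and protein toxins, proteome-to-transcriptome
    peptide mapping with target-decoy FDR filtering, and a seeded synthetic
    venom-gland dataset generator with recorded ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
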