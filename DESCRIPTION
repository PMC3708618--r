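Package: pbsvr
Title: Protein Block Realignment and Classification of Structurally
    Variable Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Compares pairs of homologous protein structures through the
    Protein Block (PB) structural alphabet. Backbones are encoded as
    16-letter PB sequences from phi/psi dihedrals, a structure-based
    sequence alignment is partitioned into structurally conserved regions
    (SCRs, superposed C-alpha distance <= 3 Angstrom) and structurally
    variable regions (SVRs, runs of >= 3 columns above the threshold),
    and each SVR's PB subsequences are globally realigned with a PB
    substitution matrix. A normalized PB alignment score with an
    inclusive cutoff of -0.42 separates conformationally similar SVRs
    (same local conformation, different rigid-body orientation) from
    genuinely dissimilar ones. Includes rigid-body least-squares
    superposition, RMSD and a length-aware structural distance metric,
    annotated alignment flat files, superposed coordinate output, and a
    synthetic backbone-pair generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
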