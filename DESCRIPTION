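Package: ldlrstruct
Title: Structure-Based Interpretation of LDLR Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates missense variants in the low-density lipoprotein
    receptor (LDLR) with structural roles derived from three-dimensional
    models of the receptor in its extracellular and endosomal states:
    disulfide-bond membership, calcium-coordination geometry, hydrophobic-core
    burial, sequence conservation and glycosylation-site proximity. Classifies
    per-condition folding stability changes (ddG_fold) with fixed significance
    thresholds, categorises condition-specific stability differences, computes
    model-quality metrics (Ramachandran fractions, hydrogen-bond participation,
    atomic clash rate, contact-potential z-scores against decoys), and produces
    summary statistics relating clinical classifications to predicted
    structural impact. Includes generators for fully synthetic mini-domain
    structures, alignments and variant tables with machine-readable planted
    truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
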