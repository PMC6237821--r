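Package: mfn2sev
Title: Clinical Severity Scoring and Structural Concordance for MFN2 GTPase-Domain Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genotype-phenotype analysis of missense mutations in
    the GTPase domain of mitofusin 2 (MFN2), the gene mutated in
    Charcot-Marie-Tooth disease type 2A (CMT2A). Implements a rule-based
    clinical severity scale for structured patient records, per-position
    grouping of missense substitutions, severity ordering chains and their
    concordance with structural-impairment orderings, and a static
    residue-interaction module (salt bridges, aromatic stacking,
    hydrophobic contacts) over PDB coordinates as a surrogate for
    molecular-modelling severity evidence. Bundles the curated 26-mutation
    catalogue with clinical records and ordering annotations, and
    seed-controlled synthetic generators for every input so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
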