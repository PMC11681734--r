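Package: xlps
Title: Cross-Species Comparison of Blood Responses to Bacterial Endotoxin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Comparative analysis of whole-blood leukocyte transcriptomes and
    plasma proteomes across mammalian species that differ in sensitivity to
    bacterial lipopolysaccharide (LPS). Translates per-species gene abundances
    into a shared human-ortholog space via a many-to-many redistribution rule,
    tests baseline and LPS-response differential expression between sensitive
    and resilient species groups with species-level blocking and
    empirical-Bayes variance moderation, screens for genes with completely
    divergent expression or response between the groups (with a one-missing
    annotation tolerance), and classifies discriminating plasma proteins by a
    three-tier presence/abundance cascade. Includes a synthetic-data generator
    that emulates the paired, blocked multi-species study design with known
    ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
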