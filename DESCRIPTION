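Package: ttgedyn
Title: Longitudinal Gut Microbiota Dynamics from PCR-TTGE Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 16S rDNA PCR-TTGE (temporal temperature
    gradient gel electrophoresis) fingerprints of longitudinal stool samples,
    aimed at the follow-up of dominant gut microbiota in very preterm infants.
    Provides gel-lane standardization against internal migration standards,
    heteroduplex-artifact flagging, band affiliation to species-level
    operational taxonomic units (SLOTUs) by diversity-ladder co-migration or
    99 percent 16S sequence identity, roll-up to genus/family (GLOTU) and
    phylum/class (PLOTU) groups, ordinal 0-3 semi-quantitative scoring,
    week-binned colonization statistics with transient/persistent
    classification, summary reporting, and a synthetic cohort and gel
    simulator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
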