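Package: fhburden
Title: Rare-Variant Burden Testing and LDL-C Polygenic Scoring for
    Familial Hypercholesterolaemia Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-discovery pipeline for mutation-negative familial
    hypercholesterolaemia (FH) exome cohorts. Reads case and control
    variant calls (VCF) with an external annotation table, flags rare
    (panel frequency < 0.5%), novel (frequency 0) and functional
    variants, screens cases against a catalogue of known FH mutations
    in LDLR, APOB, PCSK9 and LDLRAP1, computes the weighted 12-SNP
    LDL-C polygenic score with the APOE haplotype component and
    classifies polygenic hypercholesterolaemia by a healthy-population
    decile cutoff, and runs a gene-by-gene one-sided exact binomial
    burden test of qualifying carrier events in cases versus controls.
    Includes a synthetic cohort generator emulating the statistical
    structure the analysis assumes, so the whole pipeline can be
    exercised and calibrated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
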