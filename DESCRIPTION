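Package: hcvarclass
Title: Gene-Specific ACMG/AMP Variant Classification for Hereditary Cancer
    Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic rules engine for germline variant classification
    in hereditary cancer genes. Evaluates ACMG/AMP evidence criteria from
    locally supplied evidence bundles (population allele counts, in silico
    predictor scores, expert-panel codon context, curated functional assays),
    applying gene-specific ClinGen rule variants for ATM, CDH1, CHEK2, MLH1,
    MSH2, MSH6, PMS2, PTEN and TP53 and a general ruleset for other genes.
    Includes a loss-of-function (PVS1) decision tree with splice-prediction
    integration, Clopper-Pearson lower-bound allele-frequency comparisons with
    founder-population exclusion, CanVIG-UK style criterion-overlap exclusions,
    and a point-based five-tier classification. Ships a batch runner,
    spreadsheet/TSV report writer, and a seeded synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    zip
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
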