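Package: raveburden
Title: Rare-Variant Burden Testing and Exact Association for Targeted Gene Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control analysis of rare coding variation from targeted
    gene-panel sequencing: site-level hard quality filtering, classification
    of variants as novel or rare against population frequency databases
    (dbSNP, ESP6500, 1000 Genomes), PolyPhen-2-weighted allele-binning burden
    testing, gene and gene-category carrier prevalence, exact 2x2 inference
    (two-sided minlike and central p-values, conditional maximum-likelihood
    odds ratio with test-inverted confidence limits), and APOE
    epsilon-diplotype phenotype association. Includes a synthetic case-control
    cohort generator so the full pipeline runs and is testable without access
    to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
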