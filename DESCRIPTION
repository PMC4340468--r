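Package: pgxCDS
Title: Pharmacogenomic Star-Allele Calling and Clinical Decision Support
    Rule Reasoning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained pharmacogenomic reasoning engine. Compiles
    haplotype translation tables (star alleles defined by SNP allele
    patterns) and clinical decision support rules into cardinality-based
    logical definitions, infers star-allele diplotypes and drug-response
    phenotypes from unphased patient genotypes (23andMe raw files or VCF),
    emits matching dosing recommendations, and statically audits the
    knowledge base for indistinguishable haplotype definitions and for
    rules whose target patient populations subsume or conflict with one
    another. Includes an OWL 2 export of the knowledge base using
    qualified-cardinality class definitions, and a synthetic-data
    generator with ground truth for validating the caller.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'genotype-io.R'
    'inference.R'
    'kb-model.R'
    'owl-bridge.R'
    'rule-logic.R'
    'simkit.R'
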