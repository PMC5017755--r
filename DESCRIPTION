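Package: gentos
Title: Candidate-Gene Prioritization and Enrichment Testing for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines genome-wide association study (GWAS) summary statistics for
    association signals in a pre-specified candidate gene list, for example
    human orthologs of genes causing a phenotype in knockout mice. Gene
    regions are defined from a refFlat-derived gene store (longest transcript
    per symbol, plus a flanking window), a multiple-testing-corrected
    significance threshold is derived from the number of independent SNPs in
    those regions (windowed pairwise-r2 LD pruning of a reference genotype
    panel), sub-threshold SNP associations are extracted and annotated to
    genes, and enrichment of the number of significant genes over chance is
    quantified with a complementary cumulative binomial test validated
    against a resampling null distribution. Includes synthetic-data
    generators (gene catalogs, block-LD genotype panels, null and
    planted-signal summary files) so the whole pipeline can be exercised
    without external downloads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
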