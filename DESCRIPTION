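Package: PhenoGPC
Title: Genotype-Phenotype Correlation Analysis for HPO-Annotated Rare-Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical characterization of genotype-phenotype correlations in
    rare-disease cohorts encoded as GA4GH phenopackets. Individuals are
    partitioned into genotype classes by a Boolean predicate algebra over
    variant attributes (functional effect, exon, protein region, structural
    type) or by sex, diagnosis, or allele count. Phenotype annotations from the
    Human Phenotype Ontology are propagated by the true path rule; a rule-based
    independent-filtering heuristic prunes the hypothesis space before Fisher
    exact testing with multiple-testing correction. Continuous measurements,
    ontology-aware severity scores (counting scorer, modified de Vries score)
    and right-censored onset/mortality endpoints are tested with t, Mann-Whitney
    U, and logrank procedures. Includes seeded generators for toy ontologies and
    synthetic cohorts with planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    survival,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
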