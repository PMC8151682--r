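Package: henbone
Title: SNP Discovery and Effect Annotation for Bone-Stability Traits in
    Laying Hens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for identifying and annotating SNPs
    associated with bone breaking strength and bone mineral density in
    purebred layer lines. Genotypes are quality-controlled, oriented to
    the minor (effect) allele and naively imputed; phenotypes are
    adjusted for generation, layer line and a random sire effect by
    restricted maximum likelihood; adjusted residuals feed a
    from-scratch Boruta wrapper around random-forest regression that
    classifies SNPs as confirmed, tentative or rejected via shadow
    attributes and binomial hit tests; confirmed SNPs are mapped to
    protein-coding genes within a 5 kb window; per-SNP allele
    substitution, additive and dominance effects are estimated from
    mixed-model least-squares means; and candidate gene lists are tested
    for over-representation against user-supplied gene sets. A synthetic
    data generator with full truth bookkeeping emulates the study design
    (four layer lines, two generations, sire families, planted QTL) for
    calibration and recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    ranger,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
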