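#!/usr/bin/env Rscript
# Stage 4: Boruta SNP selection.
#
# For each trait, wraps a random-forest regressor (500 trees, impurity
# importance) in the Boruta shadow-attribute procedure: each iteration
# adds a permuted copy of every active SNP, scores a hit for SNPs whose
# importance beats the 99th percentile of the shadow importances, and
# classifies SNPs by exact binomial tests on the accumulated hits
# (Bonferroni-corrected by the number of active SNPs). Writes the
# per-SNP status tables and compares confirmed SNPs with the planted QTL.

suppressMessages(library(henbone))

seed <- 20210502
demo <- "results/demo"
out <- "results/pipeline"
traits <- c("Tib_BBS", "Tib_BMD")

g <- read_genotypes(file.path(out, "genotypes_oriented.tsv"))
g$oriented <- TRUE  # stage 2 wrote oriented codes
pheno <- read.csv(file.path(out, "phenotypes_adjusted.csv"))
truth <- read_truth(file.path(demo, "truth.json"))

for (tr in traits) {
  resp <- pheno[[paste0("resid_", tr)]][match(rownames(g$codes),
                                              pheno$hen_id)]
  cfg <- boruta_config(perc = 99, alpha = 0.05,
                       seed = derive_seed(seed, paste0("select:", tr)))
  res <- suppressWarnings(boruta_run(g, resp, cfg))
  print(res)
  conf <- confirmed_snps(res)
  planted <- truth[[tr]]$qtl$snp_id
  cat(sprintf("  %s: %d/%d planted QTL confirmed (%s)\n", tr,
              sum(planted %in% conf), length(planted),
              paste(intersect(planted, conf), collapse = ", ")))
  write.table(res$statuses, file.path(out, paste0("boruta_", tr, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
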