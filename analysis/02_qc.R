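#!/usr/bin/env Rscript
# Stage 2: genotype quality control, imputation and orientation.
#
# Filters in the fixed order non-autosomal SNPs -> SNP call rate >= 99%
# -> animal call rate >= 95%, then draws each missing call from the
# SNP's within-line genotype distribution and orients every SNP to its
# minor (effect) allele. Writes the QC report, the oriented genotype
# matrix (TSV) and the per-SNP metadata with effect-allele frequencies.

suppressMessages(library(henbone))

seed <- 20210502
demo <- "results/demo"
out <- "results/pipeline"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

g <- read_genotypes(file.path(demo, "genotypes.vcf"))
pheno <- read_phenotypes(file.path(demo, "phenotypes.csv"))
cat(sprintf("Read %d hens x %d SNPs (%.2f%% missing calls)\n",
            nrow(g$codes), ncol(g$codes), 100 * mean(is.na(g$codes))))

gq <- apply_qc(g)
print(qc_report(gq))

lines <- pheno$line[match(rownames(gq$codes), pheno$hen_id)]
gi <- naive_impute(gq, lines = lines, seed = derive_seed(seed, "impute"))
go <- suppressWarnings(orient_minor_allele(gi))
cat(sprintf("After QC: %d hens x %d SNPs; median effect-allele frequency %.3f\n",
            nrow(go$codes), ncol(go$codes), median(go$snps$ea_freq)))

write_genotypes(go, file.path(out, "genotypes_oriented.tsv"), format = "tsv")
write.table(qc_report(go), file.path(out, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(go$snps, file.path(out, "snps_oriented.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
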