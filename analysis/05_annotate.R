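#!/usr/bin/env Rscript
# Stage 5: gene-window annotation of confirmed SNPs.
#
# Maps each trait's confirmed SNPs to protein-coding genes whose body,
# extended by 5 kb on both sides, contains the SNP; labels hits
# intragenic / upstream / downstream relative to gene strand; and counts
# the overlap of the per-trait gene lists (Venn regions).

suppressMessages(library(henbone))

demo <- "results/demo"
out <- "results/pipeline"
traits <- c("Tib_BBS", "Tib_BMD")

genes <- read_gff3(file.path(demo, "genes.gff3"))
snps <- read.delim(file.path(out, "snps_oriented.tsv"))
cat(sprintf("Gene models: %d protein-coding genes\n", length(genes)))

gene_lists <- list()
for (tr in traits) {
  b <- read.delim(file.path(out, paste0("boruta_", tr, ".tsv")))
  conf <- b$snp_id[b$status == "confirmed"]
  hits <- map_snps_to_genes(snps[snps$snp_id %in% conf, ], genes,
                            window_bp = 5000)
  gene_lists[[tr]] <- unique(hits$gene_id)
  cat(sprintf("%s: %d confirmed SNPs -> %d gene hits (%d genes; %s)\n",
              tr, length(conf), nrow(hits), length(gene_lists[[tr]]),
              paste(names(table(hits$location)),
                    table(hits$location), sep = ":", collapse = ", ")))
  write.table(hits, file.path(out, paste0("gene_hits_", tr, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

vc <- venn_counts(gene_lists)
print(vc)
write.table(vc, file.path(out, "venn_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
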