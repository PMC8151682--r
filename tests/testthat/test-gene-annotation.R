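write_test_gff3 <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF3 reading keeps only protein-coding genes and checks coordinates", {
  f <- write_test_gff3(c(
    "1\ttest\tgene\t100\t500\t.\t+\t.\tID=g1;biotype=protein_coding;Name=ALPHA",
    "1\ttest\tgene\t1000\t2000\t.\t-\t.\tID=g2;biotype=lncRNA;Name=BETA",
    "2\ttest\tgene\t300\t900\t.\t+\t.\tID=g3;biotype=protein_coding;Name=GAMMA",
    "2\ttest\texon\t300\t400\t.\t+\t.\tID=e1;Parent=g3"))
  genes <- read_gff3(f)
  expect_equal(length(genes), 2L)
  expect_setequal(S4Vectors::mcols(genes)$gene_id, c("g1", "g3"))
  expect_setequal(S4Vectors::mcols(genes)$name, c("ALPHA", "GAMMA"))

  bad <- write_test_gff3(
    "1\ttest\tgene\t500\t100\t.\t+\t.\tID=g1;biotype=protein_coding")
  expect_error(read_gff3(bad))
})

test_that("window mapping honours boundaries, strand and locations", {
  genes <- GenomicRanges::GRanges("1", IRanges::IRanges(15000, 18000),
                                  strand = "+")
  S4Vectors::mcols(genes)$gene_id <- "g1"
  S4Vectors::mcols(genes)$name <- "g1"
  snps <- data.frame(
    snp_id = c("in_body", "up500", "down1", "edge_lo", "past_lo", "edge_hi"),
    chrom = "1",
    pos = c(16000, 14500, 18001, 15000 - 5000, 15000 - 5001, 18000 + 5000))
  hits <- map_snps_to_genes(snps, genes, window_bp = 5000)
  got <- setNames(hits$location, hits$snp_id)
  expect_equal(got[["in_body"]], "intragenic")
  expect_equal(got[["up500"]], "upstream")
  expect_equal(got[["down1"]], "downstream")
  expect_true(all(c("edge_lo", "edge_hi") %in% hits$snp_id))  # inclusive
  expect_false("past_lo" %in% hits$snp_id)     # one bp beyond the window
  expect_equal(hits$distance[hits$snp_id == "up500"], 500L)
  expect_equal(hits$distance[hits$snp_id == "in_body"], 0L)
  expect_equal(hits$distance[hits$snp_id == "down1"], 1L)

  # minus strand swaps up/downstream labels
  GenomicRanges::strand(genes) <- "-"
  hits_m <- map_snps_to_genes(snps, genes, window_bp = 5000)
  got_m <- setNames(hits_m$location, hits_m$snp_id)
  expect_equal(got_m[["up500"]], "downstream")
  expect_equal(got_m[["down1"]], "upstream")

  expect_error(map_snps_to_genes(snps, genes, window_bp = -1), "non-negative")
})

test_that("mapping equals a brute-force scan and is shift/window monotone", {
  set.seed(33)
  genes_df <- data.frame(gene_id = sprintf("g%02d", 1:10),
                         chrom = sample(1:3, 10, TRUE),
                         start = sample(1:80000, 10))
  genes_df$end <- genes_df$start + sample(2000:6000, 10)
  genes <- GenomicRanges::GRanges(genes_df$chrom,
                                  IRanges::IRanges(genes_df$start,
                                                   genes_df$end))
  S4Vectors::mcols(genes)$gene_id <- genes_df$gene_id
  S4Vectors::mcols(genes)$name <- genes_df$gene_id
  snps <- data.frame(snp_id = sprintf("s%02d", 1:50),
                     chrom = sample(1:3, 50, TRUE),
                     pos = sample(1:90000, 50))
  key <- function(h) sort(paste(h$snp_id, h$gene_id))

  for (w in c(0, 5000)) {
    hits <- map_snps_to_genes(snps, genes, w)
    expect_equal(key(hits), key(oracle_gene_hits(snps, genes_df, w)))
  }
  # shifting every coordinate by a constant leaves hits unchanged
  shift <- 12345
  genes_s <- GenomicRanges::shift(genes, shift)
  snps_s <- transform(snps, pos = pos + shift)
  expect_equal(key(map_snps_to_genes(snps_s, genes_s, 5000)),
               key(map_snps_to_genes(snps, genes, 5000)))
  # window monotonicity
  h1 <- key(map_snps_to_genes(snps, genes, 1000))
  h2 <- key(map_snps_to_genes(snps, genes, 5000))
  expect_true(all(h1 %in% h2))
})

test_that("venn regions partition the union", {
  vc <- venn_counts(list(X = c("A", "B"), Y = c("B", "C")))
  expect_equal(setNames(vc$count, vc$region),
               c(X = 1L, Y = 1L, `X&Y` = 1L))

  same <- replicate(4, sprintf("g%d", 1:7), simplify = FALSE)
  names(same) <- LETTERS[1:4]
  vc4 <- venn_counts(same)
  expect_equal(sum(vc4$count), 7L)
  expect_equal(vc4$count[vc4$region == "A&B&C&D"], 7L)

  # brute-force membership enumeration on random sets
  set.seed(44)
  sets <- lapply(1:4, function(i) sample(sprintf("g%03d", 1:200), 50))
  names(sets) <- paste0("T", 1:4)
  vc <- venn_counts(sets)
  expect_equal(sum(vc$count), length(unique(unlist(sets))))
  for (i in seq_len(nrow(vc))) {
    members <- strsplit(vc$region[i], "&", fixed = TRUE)[[1]]
    outside <- setdiff(names(sets), members)
    manual <- Reduce(intersect, sets[members])
    for (o in outside) manual <- setdiff(manual, sets[[o]])
    expect_equal(vc$count[i], length(manual))
  }
  expect_error(venn_counts(list()), "empty")
  expect_error(venn_counts(list(c("A"))), "named")
})
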