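test_that("generator is deterministic and honours missing_rate", {
  cfg <- sim_config(n_hens = 60, n_snps = 40, n_sires = 12, n_qtl = 2,
                    missing_rate = 0, seed = 7)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$codes, g2$codes)
  expect_identical(g1$snps, g2$snps)
  expect_false(anyNA(g1$codes))

  cfg_m <- sim_config(n_hens = 60, n_snps = 40, n_sires = 12,
                      missing_rate = 0.2, seed = 7)
  gm <- simulate_genotypes(cfg_m)
  expect_gt(sum(is.na(gm$codes)), 0)

  s1 <- simulate_phenotypes(g1, cfg)
  s2 <- simulate_phenotypes(g2, cfg)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth$qtl, s2$truth$qtl)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_hens = 0), "n_hens")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(sire_sd = -1), "sire_sd")
  expect_error(sim_config(line_maf_ranges = rep(list(c(0, 0.5)), 4)),
               "line_maf_ranges")
  expect_error(sim_config(line_effects = c(0, 1)), "line_effects")
  expect_error(sim_config(chroms = c("1", "33")), "chroms")
  cfg <- sim_config(n_hens = 30, n_snps = 5, n_sires = 6, n_qtl = 10,
                    missing_rate = 0)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_phenotypes(g, cfg), "n_qtl")
})

test_that("single-line fixed-MAF draws calibrate to the target frequency", {
  cfg <- sim_config(n_lines = 1, n_generations = 1, n_sires = 10,
                    n_hens = 5000, n_snps = 50,
                    line_maf_ranges = list(c(0.3, 0.3)),
                    line_effects = 0, generation_effects = 0,
                    missing_rate = 0, n_qtl = 0, seed = 42)
  g <- simulate_genotypes(cfg)
  maf <- colMeans(g$codes) / 2
  # binomial sampling: at n = 10000 alleles, +-0.02 is > 4 SDs
  expect_gte(sum(abs(maf - 0.3) <= 0.02), 48)
})

test_that("within-line genotype frequencies are Hardy-Weinberg consistent", {
  cfg <- sim_config(n_lines = 1, n_generations = 1, n_sires = 10,
                    n_hens = 5000, n_snps = 100,
                    line_maf_ranges = list(c(0.1, 0.5)),
                    line_effects = 0, generation_effects = 0,
                    missing_rate = 0, n_qtl = 0, seed = 9)
  g <- simulate_genotypes(cfg)
  pvals <- vapply(seq_len(ncol(g$codes)), function(j) {
    p <- g$line_freq[j, 1]
    obs <- tabulate(g$codes[, j] + 1L, nbins = 3L)
    expe <- 5000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - expe)^2 / expe)
    pchisq(stat, df = 2, lower.tail = FALSE)
  }, 0)
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("phenotypes decompose into the recorded truth components", {
  # no variance sources: one value per line
  cfg <- sim_config(n_lines = 2, n_generations = 1, n_sires = 4, n_hens = 40,
                    n_snps = 10, n_qtl = 0, sire_sd = 0, resid_sd = 0,
                    line_effects = c(0, 7), generation_effects = 0,
                    line_maf_ranges = rep(list(c(0.2, 0.4)), 2),
                    missing_rate = 0, seed = 5)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  vals <- tapply(sim$pheno$Tib_BBS, sim$pheno$line, function(v)
    length(unique(v)))
  expect_true(all(vals == 1))

  # one QTL, a = 5, d = 0, no other variance: homozygote spread exactly 2a
  cfg1 <- sim_config(n_lines = 1, n_generations = 1, n_sires = 5,
                     n_hens = 200, n_snps = 5, n_qtl = 1, qtl_a = 5,
                     qtl_d = 0, sire_sd = 0, resid_sd = 0, line_effects = 0,
                     generation_effects = 0, missing_rate = 0,
                     line_maf_ranges = list(c(0.3, 0.3)), seed = 11)
  sim1 <- simulate_phenotypes(simulate_genotypes(cfg1), cfg1)
  code <- sim1$truth$qtl_codes[, 1]
  y <- sim1$pheno$Tib_BBS
  expect_equal(mean(y[code == 0]) - mean(y[code == 2]), 10)

  # truth record reconstructs noise-free trait values exactly
  cfg0 <- sim_config(n_hens = 80, n_snps = 30, n_sires = 12, n_qtl = 3,
                     resid_sd = 0, missing_rate = 0.01, seed = 13)
  sim0 <- simulate_phenotypes(simulate_genotypes(cfg0), cfg0)
  expect_equal(truth_expected_values(sim0$truth, sim0$pheno),
               sim0$pheno$Tib_BBS)
  expect_true(all(sim0$truth$qtl$snp_id %in% sprintf("snp%05d", 1:30)))
})

test_that("simulated gene annotation controls QTL adjacency and round-trips", {
  cfg <- sim_config(n_hens = 50, n_snps = 60, n_sires = 8, n_qtl = 4,
                    chroms = as.character(1:6), missing_rate = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  qtl <- sim$truth$qtl$snp_id
  qtl_snps <- g$snps[g$snps$snp_id %in% qtl, , drop = FALSE]

  ann1 <- simulate_gene_annotation(g, cfg, qtl, fraction_near = 1,
                                   n_genes = 15, n_sets = 4)
  hits1 <- map_snps_to_genes(qtl_snps, ann1$genes, 5000)
  expect_setequal(unique(hits1$snp_id), qtl)

  ann0 <- simulate_gene_annotation(g, cfg, qtl, fraction_near = 0,
                                   n_genes = 15, n_sets = 4)
  hits0 <- map_snps_to_genes(qtl_snps, ann0$genes, 5000)
  expect_equal(nrow(hits0), 0)

  # every gene in exactly one set
  expect_setequal(unlist(ann1$sets), S4Vectors::mcols(ann1$genes)$gene_id)
  expect_equal(sum(lengths(ann1$sets)), 15)

  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann1$genes, f)
  back <- read_gff3(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ann1$genes))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ann1$genes))
  expect_setequal(S4Vectors::mcols(back)$gene_id,
                  S4Vectors::mcols(ann1$genes)$gene_id)

  # impossible placement errors
  tiny <- sim_config(n_hens = 50, n_snps = 60, n_sires = 8,
                     chroms = "1", chrom_length = 20000, missing_rate = 0,
                     seed = 21)
  gt <- simulate_genotypes(tiny)
  expect_error(simulate_gene_annotation(gt, tiny, character(),
                                        n_genes = 50, n_sets = 2),
               "too small")
})

test_that("truth records survive a JSON round trip", {
  cfg <- sim_config(n_hens = 40, n_snps = 20, n_sires = 8, n_qtl = 2,
                    missing_rate = 0, seed = 31)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)[["Tib_BBS"]]
  expect_equal(back$qtl$snp_id, sim$truth$qtl$snp_id)
  expect_equal(back$sire_effects, sim$truth$sire_effects)
  expect_equal(unname(as.matrix(back$qtl_codes)),
               unname(sim$truth$qtl_codes))
})
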