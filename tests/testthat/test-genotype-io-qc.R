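sim_small <- function(seed = 3, missing_rate = 0.05) {
  cfg <- sim_config(n_hens = 30, n_snps = 15, n_sires = 6, n_qtl = 0,
                    chroms = as.character(1:3), missing_rate = missing_rate,
                    seed = seed)
  simulate_genotypes(cfg)
}

test_that("VCF and TSV writers round-trip the simulator output", {
  g <- sim_small()
  for (fmt in c("vcf", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_genotypes(g, f, format = fmt)
    back <- read_genotypes(f)
    expect_equal(unname(back$codes), unname(g$codes))
    expect_equal(back$snps$snp_id, g$snps$snp_id)
    expect_equal(back$snps$chrom, g$snps$chrom)
    expect_equal(back$snps$pos, g$snps$pos)
    expect_equal(back$snps$allele_a, g$snps$allele_a)
    expect_false(back$oriented)
  }
})

test_that("VCF reader counts ALT copies and skips non-biallelic records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "h1", "h2", "h3", sep = "\t"),
    paste("1", "100", "s1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "s2", "C", "G,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/1", sep = "\t"),
    paste("2", "300", "s3", "T", "C", ".", "PASS", ".", "GT",
          "./.", "0|1", "1|1", sep = "\t")), f)
  expect_warning(g <- read_genotypes(f), "1 non-biallelic")
  expect_equal(ncol(g$codes), 2L)
  expect_equal(unname(g$codes[, "s1"]), c(0, 1, 2))
  expect_equal(unname(g$codes[, "s3"]), c(NA, 1, 2))
})

test_that("QC filters match brute-force call-rate arithmetic on a toy matrix", {
  # 6 animals x 6 SNPs, snp6 on a non-autosome, crafted missingness
  codes <- matrix(0, 6, 6, dimnames = list(paste0("a", 1:6), paste0("s", 1:6)))
  codes[1:3, 1] <- NA      # s1 call rate 3/6
  codes[1, 2] <- NA        # s2 call rate 5/6
  codes[4:6, 3] <- NA      # s3 call rate 3/6
  codes[2, 4] <- NA        # s4 call rate 5/6
  snps <- data.frame(snp_id = paste0("s", 1:6), chrom = c(1, 1, 2, 2, 3, 40),
                     pos = 1:6 * 100, allele_a = "A", allele_b = "C")
  g <- genotype_matrix(codes, snps)
  gq <- apply_qc(g, snp_call_rate = 0.8, animal_call_rate = 0.7)
  # brute force: autosome drops s6; call rates 0.5,0.833,0.5,0.833,1 -> keep s2,s4,s5
  expect_setequal(gq$snps$snp_id, c("s2", "s4", "s5"))
  # animal rates on retained SNPs: a1 misses s2 -> 2/3; a2 misses s4 -> 2/3
  expect_setequal(rownames(gq$codes), paste0("a", 3:6))
  rep <- qc_report(gq)
  expect_equal(rep$n_removed, c(1L, 2L, 2L))
  expect_true(all(rep$n_in == rep$n_removed + rep$n_retained))

  # idempotence
  gq2 <- apply_qc(gq, snp_call_rate = 0.8, animal_call_rate = 0.7)
  expect_identical(gq2$codes, gq$codes)

  # threshold boundary: one SNP missing 2/100 animals fails a 0.99 threshold
  big <- matrix(1, 100, 2, dimnames = list(NULL, c("keep", "drop")))
  big[1:2, 2] <- NA
  gb <- genotype_matrix(big, data.frame(snp_id = c("keep", "drop"), chrom = 1,
                                        pos = c(1, 2), allele_a = "A",
                                        allele_b = "C"))
  expect_equal(apply_qc(gb)$snps$snp_id, "keep")

  expect_error(apply_qc(g, snp_call_rate = 1.01), "nothing left")
})

test_that("minor-allele orientation reproduces published effect-allele frequencies", {
  # genotype counts from two published candidate loci
  mk_codes <- function(n_aa, n_ab, n_bb) c(rep(0, n_aa), rep(1, n_ab),
                                           rep(2, n_bb))
  codes <- cbind(snpA = mk_codes(219, 199, 109),   # C minor over T
                 mono = rep(0, 527))
  g <- toy_genotypes(codes, oriented = FALSE)
  expect_warning(go <- orient_minor_allele(g), "monomorphic")
  expect_equal(round(go$snps$ea_freq[1], 2), 0.40)
  expect_equal(go$snps$ea_freq[1], (199 + 2 * 109) / (2 * 527))
  expect_equal(go$snps$ea_freq[2], 0)
  gb <- toy_genotypes(cbind(snpB = mk_codes(202, 156, 166)),
                      oriented = FALSE)
  gob <- orient_minor_allele(gb)
  expect_equal(round(gob$snps$ea_freq[1], 2), 0.47)
  expect_true(all(go$snps$ea_freq <= 0.5))
  expect_true(go$oriented)
})

test_that("orientation flips high-frequency columns and is an involution", {
  codes <- cbind(flipme = c(2, 2, 2, 1, 0), keep = c(0, 0, 1, 1, 2))
  g <- toy_genotypes(codes, oriented = FALSE)
  go <- orient_minor_allele(g)
  expect_equal(unname(go$codes[, "flipme"]), c(0, 0, 0, 1, 2))
  expect_equal(unname(go$codes[, "keep"]), c(0, 0, 1, 1, 2))
  expect_equal(go$snps$ea[1], "A")  # allele A became the effect allele
  # flipping twice restores the original codes
  twice <- 2 - (2 - g$codes[, "flipme"])
  expect_equal(twice, g$codes[, "flipme"])

  # tie at 0.5: effect allele is the lexicographically smaller string
  tie <- toy_genotypes(cbind(t1 = c(0, 1, 1, 2)), oriented = FALSE)
  got <- orient_minor_allele(tie)
  expect_equal(got$snps$ea, "A")
  expect_equal(unname(got$codes[, 1]), c(2, 1, 1, 0))
})

test_that("naive imputation preserves observed data and source frequencies", {
  g <- sim_small(missing_rate = 0)
  expect_identical(naive_impute(g, seed = 1)$codes, g$codes)

  # degenerate SNP: all observed codes 0 -> imputed 0
  codes <- cbind(s1 = c(rep(0, 8), NA, NA))
  gi <- naive_impute(toy_genotypes(codes, oriented = FALSE), seed = 2)
  expect_equal(unname(gi$codes[, 1]), rep(0, 10))

  # large sample: imputed genotype distribution matches source frequencies
  src <- c(rep(0, 2450), rep(1, 2100), rep(2, 450))       # 0.49/0.42/0.09
  codes <- cbind(s1 = c(src, rep(NA_real_, 10000)))
  gbig <- toy_genotypes(codes, oriented = FALSE)
  gimp <- naive_impute(gbig, seed = 3)
  imputed <- gimp$codes[5001:15000, 1]
  counts <- tabulate(imputed + 1L, nbins = 3L)
  probs <- c(0.49, 0.42, 0.09)
  for (k in 1:3) {
    ci <- qbinom(c(0.005 / 3, 1 - 0.005 / 3), 10000, probs[k])
    expect_gte(counts[k], ci[1])
    expect_lte(counts[k], ci[2])
  }
  expect_false(anyNA(gimp$codes))

  # within-line frequencies drive the draws; empty line cells fall back
  codes <- cbind(s1 = c(0, 0, NA, 2, 2, NA))
  gl <- toy_genotypes(codes, oriented = FALSE)
  gl$samples$line <- c(1, 1, 1, 2, 2, 2)
  gli <- naive_impute(gl, seed = 4)
  expect_equal(unname(gli$codes[3, 1]), 0)  # line 1 only ever saw 0
  expect_equal(unname(gli$codes[6, 1]), 2)
})
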