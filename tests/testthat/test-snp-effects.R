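test_that("contrast arithmetic reproduces the published candidate effects", {
  tab <- candidate_effect_contrasts()
  pick <- function(snp, trait) tab[tab$snp_id == snp & tab$trait == trait, ]
  # additive effect = half the homozygote difference
  expect_equal(pick("AX-75597497", "Hum_BBS")$a, 12.0, tolerance = 0.011)
  expect_equal(pick("AX-75711229", "Tib_BBS")$a, -16.70, tolerance = 0.011)
  expect_equal(pick("AX-77091655", "Hum_BBS")$a, -7.10, tolerance = 0.011)
  expect_equal(pick("AX-77113061", "Tib_BMD")$a, -0.01, tolerance = 0.0051)
  expect_equal(pick("AX-76351898", "Hum_BMD")$a, -0.02, tolerance = 0.0051)
  # dominance effect = heterozygote minus homozygote midpoint
  expect_equal(pick("AX-76351785", "Hum_BBS")$d, -2.81, tolerance = 0.011)
  expect_equal(pick("AX-77091655", "Hum_BBS")$d, -4.38, tolerance = 0.011)
  expect_equal(pick("AX-77113061", "Tib_BMD")$d, 0.011, tolerance = 0.0011)
  # identity: equal genotypic values give a = d = 0
  expect_equal(unlist(additive_dominance(5, 5, 5)), c(a = 0, d = 0))
})

test_that("published genotype counts reproduce the effect-allele frequencies", {
  info <- published_candidate_info()
  computed <- ea_freq_from_counts(info$n_AA, info$n_AB, info$n_BB)
  expect_true(all(abs(computed - info$ea_freq) <= 0.01))
  expect_true(all(computed <= 0.5))
})

toy_effect_data <- function() {
  # perfectly linear genotype effect, one line/generation, one sire
  codes <- cbind(s1 = rep(c(0, 1, 2), each = 3))
  g <- toy_genotypes(codes, samples = data.frame(hen_id = sprintf("h%d", 1:9)),
                     oriented = TRUE)
  rownames(g$codes) <- sprintf("h%d", 1:9)
  pheno <- data.frame(hen_id = sprintf("h%d", 1:9), generation = 1, line = 1,
                      sire_id = "only", Tib_BBS = 10 + 2 * rep(0:2, each = 3))
  list(g = g, pheno = pheno)
}

test_that("single-marker regression recovers a perfect allele substitution", {
  td <- toy_effect_data()
  smr <- fit_smr(td$g, td$pheno, "s1", "Tib_BBS")
  expect_equal(smr$beta, 2.0, tolerance = 1e-10)
  expect_equal(smr$beta_std, 1.0, tolerance = 1e-10)
  expect_equal(smr$n_used, 9)
  expect_true(smr$estimable)

  # zero genotype variance flags a non-estimable result
  g0 <- td$g
  g0$codes[, 1] <- 1
  expect_warning(s0 <- fit_smr(g0, td$pheno, "s1", "Tib_BBS"), "variance")
  expect_false(s0$estimable)
  expect_true(is.na(s0$beta))
})

test_that("DRM least-squares means obey the a/d contrast identities", {
  td <- toy_effect_data()
  drm <- fit_drm(td$g, td$pheno, "s1", "Tib_BBS")
  expect_equal(drm$lsm$lsm, c(10, 12, 14), tolerance = 1e-10)
  expect_equal(unname(drm$a["estimate"]), -2, tolerance = 1e-10)
  expect_equal(unname(drm$d["estimate"]), 0, tolerance = 1e-10)
  # identities hold exactly within the same fit
  ad <- additive_dominance(drm$lsm$lsm[1], drm$lsm$lsm[2], drm$lsm$lsm[3])
  expect_equal(unname(drm$a["estimate"]), ad$a, tolerance = 1e-12)
  expect_equal(unname(drm$d["estimate"]), ad$d, tolerance = 1e-12)
})

test_that("DRM matches the emmeans reference grid on a mixed-model fit", {
  skip_if_not_installed("emmeans")
  cfg <- sim_config(n_hens = 400, n_snps = 6, n_sires = 40, n_qtl = 1,
                    qtl_a = 8, qtl_d = 3, missing_rate = 0, seed = 61)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  go <- orient_minor_allele(g)
  snp <- sim$truth$qtl$snp_id[1]
  drm <- fit_drm(go, sim$pheno, snp, "Tib_BBS")

  df <- data.frame(y = sim$pheno$Tib_BBS,
                   generation = factor(sim$pheno$generation),
                   line = factor(sim$pheno$line),
                   sire = factor(sim$pheno$sire_id),
                   geno = factor(c("AA", "AB", "BB")[go$codes[, snp] + 1],
                                 levels = c("AA", "AB", "BB")))
  fit <- lme4::lmer(y ~ generation + line + geno + (1 | sire), data = df,
                    REML = TRUE)
  em <- as.data.frame(emmeans::emmeans(fit, "geno", lmer.df = "asymptotic"))
  expect_equal(drm$lsm$lsm, em$emmean, tolerance = 1e-6)
  expect_equal(drm$lsm$se, em$SE, tolerance = 1e-6)
})

test_that("letter displays agree with brute-force clique lettering", {
  pm <- matrix(1, 3, 3, dimnames = list(c("AA", "AB", "BB"),
                                        c("AA", "AB", "BB")))
  expect_equal(unname(sig_letters(pm)), rep("a", 3))
  pm["AA", "BB"] <- pm["BB", "AA"] <- 0.01
  expect_equal(unname(sig_letters(pm)), c("a", "ab", "b"))

  set.seed(71)
  for (case in 1:50) {
    p <- matrix(1, 3, 3)
    vals <- runif(3)
    p[lower.tri(p)] <- vals
    p <- pmin(p, t(p))
    dimnames(p) <- list(1:3, 1:3)
    expect_equal(unname(sig_letters(p, alpha = 0.5)),
                 oracle_letters(p, alpha = 0.5),
                 info = paste("p:", paste(round(vals, 3), collapse = ",")))
  }
})

test_that("effects_report assembles tables and refuses mixed traits", {
  td <- toy_effect_data()
  smr <- fit_smr(td$g, td$pheno, "s1", "Tib_BBS")
  drm <- fit_drm(td$g, td$pheno, "s1", "Tib_BBS")
  rep <- effects_report(smr, drm)
  expect_equal(nrow(rep$smr), 1)
  expect_equal(rep$drm$lsm_AA, 10, tolerance = 1e-10)
  expect_false(is.na(rep$drm$letter_AA))
  smr2 <- smr
  smr2$trait <- "Hum_BBS"
  expect_error(effects_report(list(smr, smr2), list(drm)), "mixed traits")
})

test_that("SMR and DRM are consistent when dominance is absent", {
  cfg <- sim_config(n_hens = 1200, n_snps = 4, n_sires = 60, n_qtl = 1,
                    qtl_a = 6, qtl_d = 0, sire_sd = 3, resid_sd = 8,
                    line_maf_ranges = rep(list(c(0.3, 0.4)), 4),
                    missing_rate = 0, seed = 83)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  go <- orient_minor_allele(g)
  snp <- sim$truth$qtl$snp_id[1]
  smr <- fit_smr(go, sim$pheno, snp, "Tib_BBS", standardized = FALSE)
  drm <- fit_drm(go, sim$pheno, snp, "Tib_BBS")
  # substituting one effect-allele copy changes the mean by about -a
  expect_equal(smr$beta, -unname(drm$a["estimate"]),
               tolerance = 4 * smr$se_beta)
  expect_equal(unname(drm$a["estimate"]), 6,
               tolerance = 3 * unname(drm$a["se"]))
})
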