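#' Additive and dominance effects from genotype means
#'
#' Classical decomposition of three genotypic values: the additive effect
#' is half the difference between the two homozygote means,
#' `a = (mu_AA - mu_BB) / 2`, and the dominance effect is the deviation
#' of the heterozygote from the homozygote midpoint,
#' `d = mu_AB - (mu_AA + mu_BB) / 2`. AA denotes the homozygote of the
#' other (major) allele and BB the homozygote of the effect (minor)
#' allele, so `a` is the effect of the major allele.
#'
#' @param lsm_aa,lsm_ab,lsm_bb genotypic values (least-squares means),
#'   vectorised.
#' @return data.frame with columns `a` and `d` in trait units.
#' @export
additive_dominance <- function(lsm_aa, lsm_ab, lsm_bb) {
  data.frame(a = (lsm_aa - lsm_bb) / 2,
             d = lsm_ab - (lsm_aa + lsm_bb) / 2)
}

# assemble the per-SNP model frame: response, design factors, genotype code
.effect_frame <- function(g, pheno, snp_id, trait) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$oriented)
    stop("genotype matrix must be minor-allele oriented for effect models")
  if (!snp_id %in% colnames(g$codes)) stop("unknown SNP id: ", snp_id)
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not in phenotype table")
  idx <- match(pheno$hen_id, rownames(g$codes))
  df <- data.frame(y = pheno[[trait]],
                   generation = factor(pheno$generation),
                   line = factor(pheno$line),
                   sire = factor(pheno$sire_id),
                   code = g$codes[idx, snp_id])
  df <- droplevels(df[complete.cases(df[c("y", "code")]), , drop = FALSE])
  df
}

# fit y ~ <fixed terms> (+ (1|sire) when usable); returns coefficients,
# their covariance, the fixed-effect design rank and the RHS formula
.fit_fixed_mixed <- function(df, extra_term) {
  fixed_terms <- c("generation", "line")[c(nlevels(df$generation) > 1,
                                           nlevels(df$line) > 1)]
  fixed_terms <- c(fixed_terms, extra_term)
  rhs <- paste(fixed_terms, collapse = " + ")
  sire_usable <- nlevels(df$sire) >= 2 && nlevels(df$sire) < nrow(df)
  if (sire_usable) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(as.formula(paste0("y ~ ", rhs, " + (1 | sire)")),
                 data = df, REML = TRUE)))
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
  } else {
    fit <- stats::lm(as.formula(paste0("y ~ ", rhs)), data = df)
    beta <- coef(fit)
    V <- suppressWarnings(vcov(fit))  # noise-free toy fits warn in summary.lm
  }
  list(beta = beta, V = V, rank = length(beta), n = nrow(df),
       rhs = as.formula(paste0("~ ", rhs)), fit = fit)
}

# unweighted reference-grid contrast for one genotype level: averages the
# fixed-effect design over all generation x line level combinations
.lsm_contrast <- function(fitres, df, geno_level) {
  grid <- expand.grid(generation = levels(df$generation),
                      line = levels(df$line),
                      geno = factor(geno_level, levels = levels(df$geno)))
  mm <- model.matrix(fitres$rhs, grid)
  L <- colMeans(mm)
  L[names(fitres$beta)]
}

.contrast_test <- function(L, fitres) {
  est <- sum(L * fitres$beta)
  se <- sqrt(drop(t(L) %*% fitres$V %*% L))
  df_resid <- fitres$n - fitres$rank
  t <- est / se
  p <- 2 * pt(-abs(t), df_resid)
  list(estimate = est, se = se, t = t, p = p, df = df_resid)
}

#' Allele substitution effect by single marker regression
#'
#' Mixed model with fixed generation and layer-line effects, the SNP
#' genotype code (0/1/2 copies of the effect allele) as a covariate and a
#' random sire intercept. The regression coefficient of the code is the
#' allele substitution effect per copy of the effect (minor) allele. The
#' standardised variant refits after z-scoring both response and code, so
#' the coefficient is expressed in trait standard deviations.
#' t-tests use residual degrees of freedom
#' (`n_used` minus the fixed-design rank).
#'
#' @param g oriented [genotype_matrix()].
#' @param pheno phenotype data.frame (raw trait values).
#' @param snp_id SNP to test.
#' @param trait trait column name.
#' @param standardized also fit the standardised model (default TRUE).
#' @return An `smr_result`: snp_id, trait, beta, se_beta, t_value,
#'   p_value, beta_std, se_beta_std, n_used, estimable.
#' @export
fit_smr <- function(g, pheno, snp_id, trait, standardized = TRUE) {
  df <- .effect_frame(g, pheno, snp_id, trait)
  out <- list(snp_id = snp_id, trait = trait, n_used = nrow(df),
              beta = NA_real_, se_beta = NA_real_, t_value = NA_real_,
              p_value = NA_real_, beta_std = NA_real_,
              se_beta_std = NA_real_, estimable = FALSE)
  if (nrow(df) < 3 || var(df$code) == 0) {
    warning("SNP ", snp_id, " has no genotype variance; effect not estimable")
    return(structure(out, class = "smr_result"))
  }
  fitres <- .fit_fixed_mixed(df, "code")
  L <- setNames(numeric(length(fitres$beta)), names(fitres$beta))
  L["code"] <- 1
  ct <- .contrast_test(L, fitres)
  out$beta <- ct$estimate; out$se_beta <- ct$se
  out$t_value <- ct$t; out$p_value <- ct$p
  out$estimable <- TRUE
  if (standardized) {
    dfs <- df
    dfs$y <- as.numeric(scale(dfs$y))
    dfs$code <- as.numeric(scale(dfs$code))
    fits <- .fit_fixed_mixed(dfs, "code")
    Ls <- setNames(numeric(length(fits$beta)), names(fits$beta))
    Ls["code"] <- 1
    cts <- .contrast_test(Ls, fits)
    out$beta_std <- cts$estimate; out$se_beta_std <- cts$se
  }
  structure(out, class = "smr_result")
}

#' Genotype least-squares means and additive/dominance decomposition
#'
#' Dominant-recessive model: the SNP genotype enters as a three-level
#' fixed class variable (AA = homozygote of the other/major allele,
#' AB = heterozygote, BB = homozygote of the effect/minor allele)
#' alongside fixed generation and layer-line effects and a random sire
#' intercept. Least-squares means average the fixed design equally over
#' generation and line levels (unweighted reference grid); the three
#' pairwise genotype contrasts are t-tested with Bonferroni factor 3, and
#' the additive and dominance effects are the [additive_dominance()]
#' contrasts of the same fit with SEs from the contrast covariance.
#' Genotype classes without observations yield missing LSMs and
#' non-estimable contrasts.
#'
#' @inheritParams fit_smr
#' @return A `drm_result`: `lsm` data.frame (genotype, lsm, se),
#'   `pairwise` data.frame (contrast, estimate, se, t, p_raw, p_adj),
#'   `a` and `d` rows (estimate, se, t, p), n_used, estimable.
#' @export
fit_drm <- function(g, pheno, snp_id, trait) {
  df <- .effect_frame(g, pheno, snp_id, trait)
  geno_levels <- c("AA", "AB", "BB")
  df$geno <- factor(geno_levels[df$code + 1], levels = geno_levels)
  df$geno <- droplevels(df$geno)
  present <- levels(df$geno)
  out <- list(snp_id = snp_id, trait = trait, n_used = nrow(df),
              lsm = data.frame(genotype = geno_levels, lsm = NA_real_,
                               se = NA_real_),
              pairwise = data.frame(),
              a = c(estimate = NA, se = NA, t = NA, p = NA),
              d = c(estimate = NA, se = NA, t = NA, p = NA),
              estimable = FALSE)
  if (nrow(df) < 3 || length(present) < 2) {
    warning("SNP ", snp_id, ": fewer than two genotype classes observed")
    return(structure(out, class = "drm_result"))
  }
  fitres <- .fit_fixed_mixed(df, "geno")
  Ls <- lapply(present, function(gl) .lsm_contrast(fitres, df, gl))
  names(Ls) <- present
  for (gl in present) {
    ct <- .contrast_test(Ls[[gl]], fitres)
    i <- match(gl, out$lsm$genotype)
    out$lsm$lsm[i] <- ct$estimate
    out$lsm$se[i] <- ct$se
  }
  pairs <- utils::combn(present, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    ct <- .contrast_test(Ls[[pr[1]]] - Ls[[pr[2]]], fitres)
    data.frame(contrast = paste(pr, collapse = "-"), estimate = ct$estimate,
               se = ct$se, t = ct$t, p_raw = ct$p,
               p_adj = min(1, 3 * ct$p))  # Bonferroni over 3 genotype contrasts
  })
  out$pairwise <- do.call(rbind, pw)
  if (all(geno_levels %in% present)) {
    ct_a <- .contrast_test((Ls[["AA"]] - Ls[["BB"]]) / 2, fitres)
    ct_d <- .contrast_test(Ls[["AB"]] - (Ls[["AA"]] + Ls[["BB"]]) / 2, fitres)
    out$a <- c(estimate = ct_a$estimate, se = ct_a$se, t = ct_a$t, p = ct_a$p)
    out$d <- c(estimate = ct_d$estimate, se = ct_d$se, t = ct_d$t, p = ct_d$p)
    out$estimable <- TRUE
  } else {
    warning("SNP ", snp_id, ": genotype class(es) ",
            paste(setdiff(geno_levels, present), collapse = ", "),
            " unobserved; a/d not estimable")
  }
  structure(out, class = "drm_result")
}

#' @export
print.drm_result <- function(x, ...) {
  cat(sprintf("drm_result %s / %s (n=%d): a = %.4g (SE %.3g), d = %.4g (SE %.3g)\n",
              x$snp_id, x$trait, x$n_used, x$a["estimate"], x$a["se"],
              x$d["estimate"], x$d["se"]))
  invisible(x)
}

#' Compact-letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb lettering: groups that are not significantly
#' different share at least one letter; every significant pair shares
#' none. Letters are assigned in group order.
#'
#' @param p_matrix symmetric matrix of pairwise p-values (diagonal
#'   ignored) with group dimnames.
#' @param alpha significance level (default 0.05).
#' @return Named character vector of letter strings per group.
#' @export
sig_letters <- function(p_matrix, alpha = 0.05) {
  k <- nrow(p_matrix)
  groups <- rownames(p_matrix) %||% as.character(seq_len(k))
  letters_sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!is.na(p_matrix[i, j]) && p_matrix[i, j] < alpha) {
      hit <- which(vapply(letters_sets, function(s) all(c(i, j) %in% s), TRUE))
      for (h in hit) {
        s <- letters_sets[[h]]
        letters_sets[[h]] <- setdiff(s, i)
        letters_sets <- c(letters_sets, list(setdiff(s, j)))
      }
      # absorb duplicates and sets strictly contained in another set
      letters_sets <- unique(letters_sets[lengths(letters_sets) > 0])
      keep <- !vapply(seq_along(letters_sets), function(m)
        any(vapply(seq_along(letters_sets), function(n)
          n != m && length(letters_sets[[n]]) > length(letters_sets[[m]]) &&
            all(letters_sets[[m]] %in% letters_sets[[n]]), TRUE)),
        TRUE)
      letters_sets <- letters_sets[keep]
    }
  }
  ord <- order(vapply(letters_sets, function(s)
    paste(sort(s), collapse = ","), ""))
  letters_sets <- letters_sets[ord]
  out <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(letters_sets, function(s) i %in% s, TRUE))],
           collapse = ""), "")
  setNames(out, groups)
}

#' Tabulate SMR and DRM results in the published layout
#'
#' One row per SNP: allele-substitution effect (raw and standardised)
#' from the single-marker regression, genotype LSMs with significance
#' letters from the Bonferroni-adjusted pairwise tests, and the additive
#' and dominance effects with SEs, t and p. All results in one table must
#' concern the same trait.
#'
#' @param smr_results list of [fit_smr()] results.
#' @param drm_results list of [fit_drm()] results (same SNPs/trait).
#' @param alpha significance level for the letter display.
#' @return `list(smr = data.frame, drm = data.frame)`.
#' @export
effects_report <- function(smr_results, drm_results, alpha = 0.05) {
  if (inherits(smr_results, "smr_result")) smr_results <- list(smr_results)
  if (inherits(drm_results, "drm_result")) drm_results <- list(drm_results)
  traits <- unique(c(vapply(smr_results, `[[`, "", "trait"),
                     vapply(drm_results, `[[`, "", "trait")))
  if (length(traits) > 1)
    stop("mixed traits in one effects table: ", paste(traits, collapse = ", "))
  smr <- do.call(rbind, lapply(smr_results, function(r)
    data.frame(snp_id = r$snp_id, trait = r$trait, n_used = r$n_used,
               beta = r$beta, se_beta = r$se_beta, beta_std = r$beta_std,
               se_beta_std = r$se_beta_std, t_value = r$t_value,
               p_value = r$p_value)))
  drm <- do.call(rbind, lapply(drm_results, function(r) {
    lets <- setNames(rep(NA_character_, 3), c("AA", "AB", "BB"))
    if (nrow(r$pairwise)) {
      pm <- matrix(NA_real_, 3, 3, dimnames = list(c("AA", "AB", "BB"),
                                                   c("AA", "AB", "BB")))
      for (i in seq_len(nrow(r$pairwise))) {
        pr <- strsplit(r$pairwise$contrast[i], "-", fixed = TRUE)[[1]]
        pm[pr[1], pr[2]] <- pm[pr[2], pr[1]] <- r$pairwise$p_adj[i]
      }
      present <- r$lsm$genotype[!is.na(r$lsm$lsm)]
      lets[present] <- sig_letters(pm[present, present, drop = FALSE], alpha)
    }
    data.frame(snp_id = r$snp_id, trait = r$trait, n_used = r$n_used,
               lsm_AA = r$lsm$lsm[1], se_AA = r$lsm$se[1],
               letter_AA = lets["AA"],
               lsm_AB = r$lsm$lsm[2], se_AB = r$lsm$se[2],
               letter_AB = lets["AB"],
               lsm_BB = r$lsm$lsm[3], se_BB = r$lsm$se[3],
               letter_BB = lets["BB"],
               a = r$a["estimate"], se_a = r$a["se"], t_a = r$a["t"],
               p_a = r$a["p"],
               d = r$d["estimate"], se_d = r$d["se"], t_d = r$d["t"],
               p_d = r$d["p"], row.names = NULL)
  }))
  list(smr = smr, drm = drm)
}
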