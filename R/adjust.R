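#' Fit the phenotype adjustment model for one trait
#'
#' Linear mixed model with fixed generation and layer-line effects and a
#' random sire intercept, fitted by restricted maximum likelihood:
#' trait = mu + generation + line + sire + residual. The conditional
#' residuals (observed value minus fixed-effect predictions minus the
#' sire BLUP) are the "adjusted phenotypes" used as the response in the
#' downstream SNP selection; they remove half-sib family means so the
#' selector does not rediscover population structure. Marginal residuals
#' (sire BLUP not subtracted) are available via `residual_type`.
#'
#' Fixed-effect levels are reported as deviations from their unweighted
#' level mean and `mu` as the intercept plus those level means, so the
#' summaries do not depend on the reference-level convention. Factors
#' with a single observed level drop out of the model; when the sire
#' factor is degenerate (fewer than two levels, or one level per hen) the
#' model reduces to ordinary least squares with sire variance 0.
#'
#' @param pheno phenotype data.frame with `hen_id`, `generation`, `line`,
#'   `sire_id` and the trait column.
#' @param trait name of the trait column.
#' @param residual_type `"conditional"` (default; sire BLUP subtracted)
#'   or `"marginal"`.
#' @return An `adjustment_fit`: trait, `mu`, `generation_effects`,
#'   `line_effects` (zero-centred), `sire_variance`, `resid_variance`,
#'   `sire_blups`, `residuals` (named by hen id), `n_used`, `singular`.
#' @export
fit_adjustment_model <- function(pheno, trait,
                                 residual_type = c("conditional", "marginal")) {
  residual_type <- match.arg(residual_type)
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not in phenotype table")
  df <- data.frame(hen_id = pheno$hen_id,
                   y = pheno[[trait]],
                   generation = factor(pheno$generation),
                   line = factor(pheno$line),
                   sire = factor(pheno$sire_id))
  df <- df[!is.na(df$y), , drop = FALSE]
  df <- droplevels(df)
  if (nrow(df) < 3L) stop("too few non-missing observations for trait ", trait)

  fixed_terms <- c("generation", "line")[c(nlevels(df$generation) > 1,
                                           nlevels(df$line) > 1)]
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  sire_usable <- nlevels(df$sire) >= 2 && nlevels(df$sire) < nrow(df)

  if (sire_usable) {
    fml <- as.formula(paste0("y ~ ", rhs, " + (1 | sire)"))
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
    singular <- lme4::isSingular(fit)
    if (singular) warning("sire variance estimated at the zero boundary")
    beta <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sire_var <- vc$vcov[vc$grp == "sire"]
    resid_var <- vc$vcov[vc$grp == "Residual"]
    blups <- lme4::ranef(fit)$sire
    sire_blups <- setNames(blups[[1]], rownames(blups))
    cond_resid <- setNames(residuals(fit), df$hen_id)
    marg_resid <- setNames(df$y - (model.matrix(as.formula(paste0("~ ", rhs)),
                                                df) %*% beta)[, 1], df$hen_id)
  } else {
    fml <- as.formula(paste0("y ~ ", rhs))
    fit <- stats::lm(fml, data = df)
    singular <- TRUE
    beta <- coef(fit)
    sire_var <- 0
    resid_var <- suppressWarnings(summary(fit)$sigma^2)
    sire_blups <- setNames(rep(0, nlevels(df$sire)), levels(df$sire))
    cond_resid <- marg_resid <- setNames(residuals(fit), df$hen_id)
  }

  level_effects <- function(fac) {
    lev <- levels(df[[fac]])
    if (length(lev) < 2) return(setNames(rep(0, length(lev)), lev))
    eff <- c(0, beta[paste0(fac, lev[-1])])
    setNames(eff - mean(eff), lev)
  }
  gen_eff <- level_effects("generation")
  line_eff <- level_effects("line")
  level_mean <- function(fac) {
    lev <- levels(df[[fac]])
    if (length(lev) < 2) return(0)
    mean(c(0, unname(beta[paste0(fac, lev[-1])])))
  }
  mu <- unname(beta["(Intercept)"]) + level_mean("generation") +
    level_mean("line")

  structure(list(trait = trait, mu = mu,
                 generation_effects = gen_eff, line_effects = line_eff,
                 sire_variance = sire_var, resid_variance = resid_var,
                 sire_blups = sire_blups,
                 residuals = if (residual_type == "conditional") cond_resid
                             else marg_resid,
                 residual_type = residual_type,
                 n_used = nrow(df), singular = singular),
            class = "adjustment_fit")
}

#' @export
print.adjustment_fit <- function(x, ...) {
  cat(sprintf(
    "adjustment_fit '%s': n=%d, sire var %.4g, resid var %.4g (%s residuals)\n",
    x$trait, x$n_used, x$sire_variance, x$resid_variance, x$residual_type))
  invisible(x)
}

#' Attach adjusted residuals to a phenotype table
#'
#' Adds one `resid_<trait>` column per fit; hens with a missing trait
#' value carry a missing residual.
#'
#' @param pheno phenotype data.frame.
#' @param fits a single [fit_adjustment_model()] result or a list of them.
#' @return `pheno` with residual columns appended.
#' @export
attach_residuals <- function(pheno, fits) {
  if (inherits(fits, "adjustment_fit")) fits <- list(fits)
  for (fit in fits) {
    if (!fit$trait %in% names(pheno))
      stop("fit is for trait '", fit$trait, "', absent from the phenotype table")
    col <- paste0("resid_", fit$trait)
    pheno[[col]] <- unname(fit$residuals[match(pheno$hen_id,
                                               names(fit$residuals))])
  }
  pheno
}
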