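#' Configuration for the Boruta SNP selector
#'
#' @param perc percentile of the shadow-attribute importances a SNP must
#'   beat to score a hit (default 99, i.e. effectively the best shadows).
#' @param alpha two-sided level of the binomial hit test (default 0.05).
#' @param max_iter maximum number of iterations (default 100; at least 8,
#'   the smallest count at which the exact binomial tail can decide).
#' @param n_trees trees per random-forest regressor (default 500).
#' @param mtry features tried per split in the expanded (real + shadow)
#'   matrix; `NULL` (default) uses square-root subsampling. Full-feature
#'   subsampling (`mtry = Inf`) concentrates importance on the causal
#'   feature and suppresses chance-correlated proxies, at a steep runtime
#'   cost on wide matrices.
#' @param correction `"bonferroni"` (alpha divided by the number of
#'   features still in the forest) or `"none"`.
#' @param seed master seed; per-iteration seeds are derived from it so
#'   histories are reproducible regardless of when the loop stops.
#' @param resolve_tentative `"exclude"` (default: features still
#'   undecided at `max_iter` stay tentative and are not reported as
#'   confirmed) or `"median-rule"` (confirm a tentative feature whose
#'   median importance exceeds the median of the per-iteration shadow
#'   maxima).
#' @return Validated list of class `boruta_config`.
#' @export
boruta_config <- function(perc = 99, alpha = 0.05, max_iter = 100,
                          n_trees = 500, mtry = NULL,
                          correction = c("bonferroni", "none"), seed = 1,
                          resolve_tentative = c("exclude", "median-rule")) {
  correction <- match.arg(correction)
  resolve_tentative <- match.arg(resolve_tentative)
  if (perc < 0 || perc > 100) stop("'perc' must be in [0, 100]")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (max_iter < 8) stop("'max_iter' must be at least 8")
  structure(list(perc = perc, alpha = alpha, max_iter = as.integer(max_iter),
                 n_trees = as.integer(n_trees), mtry = mtry,
                 correction = correction, seed = as.integer(seed),
                 resolve_tentative = resolve_tentative),
            class = "boruta_config")
}

#' Expand a feature matrix with shadow attributes
#'
#' Appends one shadow column per real column, each an independent row
#' permutation of its source, severing any association with the response
#' while preserving the marginal distribution. Shadow columns are named
#' `shadow_<source>`.
#'
#' @param x numeric matrix of active features (samples x features, with
#'   column names).
#' @param seed integer seed for the permutations.
#' @return Matrix with `2 * ncol(x)` columns: the originals followed by
#'   their shadows.
#' @export
make_shadow <- function(x, seed = 1) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop("no active features to shadow")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(seed)
  shadow <- apply(x, 2, sample)
  colnames(shadow) <- paste0("shadow_", colnames(x))
  cbind(x, shadow)
}

#' Score one iteration's hits against the shadow importance threshold
#'
#' The threshold is the `perc`-th percentile (linear interpolation
#' between order statistics) of this iteration's shadow importances; a
#' real feature scores a hit iff its importance is strictly greater.
#'
#' @param importances numeric vector: the `n_real` real features'
#'   importances followed by the shadow importances (one per real feature
#'   in a standard iteration, but any positive number is accepted).
#' @param n_real number of real features.
#' @param perc percentile in `[0, 100]`.
#' @return Logical hit flag per real feature.
#' @export
iteration_hits <- function(importances, n_real, perc = 99) {
  if (length(importances) <= n_real)
    stop("importance vector must contain shadow importances after the ",
         n_real, " real ones (length 2 * n_real in a standard iteration)")
  real <- importances[seq_len(n_real)]
  shadow <- importances[-seq_len(n_real)]
  threshold <- as.numeric(quantile(shadow, perc / 100, type = 7, names = FALSE))
  real > threshold
}

#' Classify features from accumulated hit counts
#'
#' Under the null a feature's hit count is Binomial(n_iter, 1/2). A
#' feature is confirmed when the upper tail `P(X >= hits)` falls below
#' `alpha/2` (Bonferroni-corrected by the number of still-active
#' features), rejected when the lower tail `P(X <= hits)` does, and
#' tentative otherwise.
#'
#' @param hits integer vector of hit counts.
#' @param n_iter iterations over which hits were accumulated.
#' @param n_active number of features still active (Bonferroni divisor).
#' @param alpha two-sided test level.
#' @param correction `"bonferroni"` or `"none"`.
#' @return Character vector: `"confirmed"`, `"rejected"` or `"tentative"`.
#' @export
decide_statuses <- function(hits, n_iter, n_active, alpha = 0.05,
                            correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (n_iter < 1) stop("n_iter must be positive")
  a <- if (correction == "bonferroni") alpha / max(n_active, 1) else alpha
  p_up <- pbinom(hits - 1, n_iter, 0.5, lower.tail = FALSE)   # P(X >= hits)
  p_down <- pbinom(hits, n_iter, 0.5)                          # P(X <= hits)
  ifelse(p_up < a / 2, "confirmed",
         ifelse(p_down < a / 2, "rejected", "tentative"))
}

#' Run Boruta all-relevant SNP selection around a random-forest regressor
#'
#' Iteratively (i) permutes every active SNP into a shadow attribute,
#' (ii) fits a random-forest regressor (impurity importance,
#' square-root feature subsampling) on the doubled matrix, (iii) counts a
#' hit for each SNP whose importance strictly exceeds the `perc`-th
#' percentile of the shadow importances, and (iv) applies the exact
#' binomial confirm/reject test to the accumulated hit counts, removing
#' rejected SNPs from the forest. Confirmed SNPs stay in the forest so
#' importances remain comparable. The loop stops when no SNP is still
#' undecided or at `max_iter`. Zero-variance SNPs never enter the forest
#' and are reported as rejected with a warning; a zero-variance response
#' yields an all-rejected result with a warning.
#'
#' @param g a minor-allele-oriented [genotype_matrix()] without missing
#'   codes, or a plain numeric feature matrix with column names.
#' @param response numeric response (adjusted phenotype residuals), one
#'   value per sample; samples with a missing response are dropped.
#' @param config a [boruta_config()].
#' @return A `boruta_result`: `statuses` data.frame (snp_id, status,
#'   hits, n_iterations_active), `importance_history` (per iteration: the
#'   active SNPs' importances plus the shadow max and `perc`-percentile),
#'   `n_iterations`, and the config.
#' @export
boruta_run <- function(g, response, config = boruta_config()) {
  stopifnot(inherits(config, "boruta_config"))
  if (inherits(g, "genotype_matrix")) {
    if (!g$oriented)
      stop("genotype matrix must be minor-allele oriented before selection")
    x <- g$codes
  } else {
    x <- as.matrix(g)
  }
  if (length(response) != nrow(x))
    stop("response length must equal the number of samples")
  keep <- !is.na(response)
  x <- x[keep, , drop = FALSE]
  y <- response[keep]
  if (anyNA(x)) stop("genotype codes contain missing values; impute first")
  snp_ids <- colnames(x)

  status <- setNames(rep("tentative", ncol(x)), snp_ids)
  hits <- setNames(rep(0L, ncol(x)), snp_ids)
  n_it <- setNames(rep(0L, ncol(x)), snp_ids)

  zero_var <- apply(x, 2, var) == 0
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance SNP(s) skipped (reported rejected)",
                    sum(zero_var)))
    status[zero_var] <- "rejected"
  }
  history <- list()
  if (var(y) == 0) {
    warning("response has zero variance; all SNPs rejected")
    status[] <- "rejected"
    return(.boruta_result(status, hits, n_it, history, 0L, config))
  }

  iter <- 0L
  while (iter < config$max_iter && any(status == "tentative")) {
    iter <- iter + 1L
    active <- names(status)[status != "rejected"]
    it_seed <- derive_seed(config$seed, sprintf("iter%04d", iter))
    xs <- make_shadow(x[, active, drop = FALSE], seed = it_seed)
    mtry <- if (is.null(config$mtry)) floor(sqrt(ncol(xs)))
            else min(ncol(xs), config$mtry)
    rf <- ranger::ranger(x = xs, y = y, num.trees = config$n_trees,
                         importance = "impurity", mtry = mtry,
                         seed = it_seed, num.threads = 1)
    imp <- rf$variable.importance
    if (any(!is.finite(imp))) stop("non-finite importances from the forest")
    hit_flags <- iteration_hits(imp, length(active), config$perc)
    hits[active] <- hits[active] + hit_flags
    n_it[active] <- n_it[active] + 1L
    shadow_imp <- imp[length(active) + seq_along(active)]
    history[[iter]] <- list(
      iteration = iter,
      importance = imp[seq_along(active)],
      shadow_max = max(shadow_imp),
      shadow_perc = as.numeric(quantile(shadow_imp, config$perc / 100,
                                        type = 7, names = FALSE)))
    undecided <- names(status)[status == "tentative"]
    new_status <- decide_statuses(hits[undecided], iter, length(active),
                                  config$alpha, config$correction)
    status[undecided] <- new_status
  }

  if (config$resolve_tentative == "median-rule" && any(status == "tentative")) {
    shadow_med <- stats::median(vapply(history, `[[`, 0, "shadow_max"))
    for (s in names(status)[status == "tentative"]) {
      imps <- unlist(lapply(history, function(h) h$importance[s]))
      if (stats::median(imps, na.rm = TRUE) > shadow_med)
        status[s] <- "confirmed"
    }
  }
  .boruta_result(status, hits, n_it, history, iter, config)
}

.boruta_result <- function(status, hits, n_it, history, n_iterations, config) {
  structure(list(
    statuses = data.frame(snp_id = names(status), status = unname(status),
                          hits = unname(hits),
                          n_iterations_active = unname(n_it)),
    importance_history = history,
    n_iterations = n_iterations,
    config = config, seed = config$seed),
    class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$statuses$status,
                      levels = c("confirmed", "tentative", "rejected")))
  cat(sprintf(
    "boruta_result: %d SNPs after %d iteration(s) — %d confirmed, %d tentative, %d rejected\n",
    nrow(x$statuses), x$n_iterations, tab["confirmed"], tab["tentative"],
    tab["rejected"]))
  invisible(x)
}

#' Confirmed SNP ids from a Boruta result
#' @param result a `boruta_result`.
#' @return Character vector of confirmed SNP ids.
#' @export
confirmed_snps <- function(result) {
  result$statuses$snp_id[result$statuses$status == "confirmed"]
}
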