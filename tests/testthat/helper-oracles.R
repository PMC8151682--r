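# Independent oracles used across the test files. Each is a deliberately
# naive implementation (brute force, enumeration or closed form) kept
# separate from the package code paths it checks.

# linear-interpolation percentile between order statistics
oracle_percentile <- function(x, perc) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * perc / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[min(hi, n)] - x[lo])
}

# O(S * G) scan for SNP-to-gene window hits
oracle_gene_hits <- function(snps, genes_df, window) {
  out <- list()
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(genes_df))) {
    if (snps$chrom[i] == genes_df$chrom[j] &&
        snps$pos[i] >= genes_df$start[j] - window &&
        snps$pos[i] <= genes_df$end[j] + window) {
      out[[length(out) + 1]] <- data.frame(snp_id = snps$snp_id[i],
                                           gene_id = genes_df$gene_id[j])
    }
  }
  if (!length(out)) return(data.frame(snp_id = character(),
                                      gene_id = character()))
  do.call(rbind, out)
}

# exact hypergeometric upper tail by term-wise enumeration (N small)
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# compact letters by maximal-clique enumeration over the
# "not significantly different" graph (small k only)
oracle_letters <- function(p_matrix, alpha = 0.05) {
  k <- nrow(p_matrix)
  adj <- is.na(p_matrix) | p_matrix >= alpha
  diag(adj) <- TRUE
  subsets <- list()
  for (size in k:1) for (s in utils::combn(k, size, simplify = FALSE)) {
    if (all(adj[s, s])) subsets[[length(subsets) + 1]] <- s
  }
  # keep maximal cliques only
  maximal <- Filter(function(s) !any(vapply(subsets, function(t)
    length(t) > length(s) && all(s %in% t) && all(adj[t, t]), TRUE)), subsets)
  maximal <- unique(maximal)
  maximal <- maximal[order(vapply(maximal, function(s)
    paste(sort(s), collapse = ","), ""))]
  vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(maximal, function(s) i %in% s, TRUE))],
           collapse = ""), "")
}

# expected-information asymptotic covariance of (sigma_s^2, sigma_e^2)
# for a balanced sire design: s families of size m, V block-diagonal
# with blocks sigma_e^2 I_m + sigma_s^2 J_m
oracle_varcomp_se <- function(sigma_s2, sigma_e2, s, m) {
  cc <- 1 / (sigma_e2 + m * sigma_s2)
  i_ss <- 0.5 * s * m^2 * cc^2
  i_se <- 0.5 * s * m * cc^2
  i_ee <- 0.5 * s * (cc^2 + (m - 1) / sigma_e2^2)
  info <- matrix(c(i_ss, i_se, i_se, i_ee), 2, 2)
  sqrt(diag(solve(info)))
}

# ordinary least squares through the normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# build a small oriented genotype_matrix from a code matrix
toy_genotypes <- function(codes, chrom = "1", pos = NULL, samples = NULL,
                          oriented = TRUE) {
  codes <- as.matrix(codes)
  p <- ncol(codes)
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("snp%02d", 1:p)
  snps <- data.frame(snp_id = colnames(codes),
                     chrom = rep(chrom, length.out = p),
                     pos = pos %||% seq(1000, by = 1000, length.out = p),
                     allele_a = "A", allele_b = "C")
  henbone::genotype_matrix(codes, snps, samples = samples, oriented = oriented)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
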