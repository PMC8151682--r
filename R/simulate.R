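#' Configuration for the synthetic laying-hen study generator
#'
#' Defaults emulate the design the analysis assumes: 524 hens from four
#' purebred layer lines and two generations, 145 sires nested within
#' line, biallelic SNPs on autosomes 1-28 with line-specific allele
#' frequencies, and one quantitative bone trait built from line and
#' generation fixed effects, a random sire effect, planted QTL with
#' additive/dominance action, and residual noise. Trait-scale defaults
#' are on the bone-breaking-strength scale (newtons); pass BMD-scale
#' values (g/cm2) to simulate a density trait.
#'
#' @param n_lines,n_generations,n_sires,n_hens design sizes.
#' @param n_snps number of simulated SNPs.
#' @param chroms autosome labels used (subset of `"1"`..`"28"`).
#' @param chrom_length length in bp of each simulated chromosome.
#' @param line_maf_ranges list of length `n_lines`; per-line `c(lo, hi)`
#'   uniform range in `(0, 0.5]` for the B-allele frequency of each SNP.
#' @param n_qtl number of planted QTL.
#' @param qtl_a,qtl_d additive and dominance effects per QTL in trait
#'   units (recycled to `n_qtl`); a hen with 0/1/2 copies of the QTL's
#'   B allele receives `+a` / `d` / `-a`.
#' @param qtl_min_maf minimum overall B-allele frequency for a SNP to be
#'   eligible as a QTL.
#' @param mean overall trait mean.
#' @param line_effects,generation_effects per-level fixed shifts.
#' @param sire_sd,resid_sd standard deviations of the random sire effect
#'   and the residual, in trait units.
#' @param missing_rate fraction of genotype calls set missing.
#' @param trait trait column name (default `"Tib_BBS"`).
#' @param seed integer master seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 4, n_generations = 2, n_sires = 145,
                       n_hens = 524, n_snps = 1000,
                       chroms = as.character(1:28), chrom_length = 2e6,
                       line_maf_ranges = NULL,
                       n_qtl = 5, qtl_a = 12, qtl_d = 4, qtl_min_maf = 0.15,
                       mean = 150,
                       line_effects = c(0, 15, -10, 5),
                       generation_effects = c(0, 8),
                       sire_sd = 6, resid_sd = 25,
                       missing_rate = 0.005, trait = "Tib_BBS", seed = 1) {
  cfg <- list(n_lines = .check_count(n_lines, "n_lines"),
              n_generations = .check_count(n_generations, "n_generations"),
              n_sires = .check_count(n_sires, "n_sires"),
              n_hens = .check_count(n_hens, "n_hens"),
              n_snps = .check_count(n_snps, "n_snps"),
              chroms = as.character(chroms), chrom_length = chrom_length,
              line_maf_ranges = line_maf_ranges %||%
                rep(list(c(0.05, 0.5)), n_lines),
              n_qtl = as.integer(n_qtl), qtl_a = qtl_a, qtl_d = qtl_d,
              qtl_min_maf = qtl_min_maf, mean = mean,
              line_effects = line_effects,
              generation_effects = generation_effects,
              sire_sd = sire_sd, resid_sd = resid_sd,
              missing_rate = missing_rate, trait = trait,
              seed = as.integer(seed))
  if (!all(cfg$chroms %in% as.character(1:28)))
    stop("invalid configuration: 'chroms' must be a subset of autosomes 1..28")
  if (length(cfg$line_maf_ranges) != cfg$n_lines)
    stop("invalid configuration: 'line_maf_ranges' must have one range per line")
  for (r in cfg$line_maf_ranges)
    if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
      stop("invalid configuration: 'line_maf_ranges' entries must lie in (0, 0.5]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid configuration: 'missing_rate' must be in [0, 1)")
  if (cfg$sire_sd < 0 || cfg$resid_sd < 0)
    stop("invalid configuration: 'sire_sd' and 'resid_sd' must be >= 0")
  if (cfg$n_qtl < 0)
    stop("invalid configuration: 'n_qtl' must be >= 0")
  if (length(cfg$line_effects) != cfg$n_lines)
    stop("invalid configuration: 'line_effects' must have one entry per line")
  if (length(cfg$generation_effects) != cfg$n_generations)
    stop("invalid configuration: 'generation_effects' needs one entry per generation")
  if (cfg$n_sires < cfg$n_lines)
    stop("invalid configuration: 'n_sires' must be at least 'n_lines'")
  structure(cfg, class = "sim_config")
}

# balanced design: lines split as evenly as possible, generations
# alternating within line, sires nested within line, hens round-robin
.sim_design <- function(cfg) {
  line <- rep(seq_len(cfg$n_lines), length.out = cfg$n_hens)
  line <- sort(line)
  sires_per_line <- diff(round(seq(0, cfg$n_sires, length.out = cfg$n_lines + 1)))
  sire_line <- rep(seq_len(cfg$n_lines), times = sires_per_line)
  sire_id <- sprintf("sire%03d", seq_len(cfg$n_sires))
  hen_sire <- character(cfg$n_hens)
  generation <- integer(cfg$n_hens)
  for (l in seq_len(cfg$n_lines)) {
    idx <- which(line == l)
    pool <- sire_id[sire_line == l]
    hen_sire[idx] <- rep(pool, length.out = length(idx))
    generation[idx] <- rep(seq_len(cfg$n_generations), length.out = length(idx))
  }
  list(samples = data.frame(hen_id = sprintf("hen%04d", seq_len(cfg$n_hens)),
                            line = line, generation = generation,
                            sire_id = hen_sire),
       sire_id = sire_id, sire_line = sire_line)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium within line
#'
#' Per SNP and line, a B-allele frequency is drawn from the line's
#' configured range; genotypes are then drawn binomially (Hardy-Weinberg
#' within line) and missing calls injected uniformly at random at
#' `missing_rate`. The complete pre-missingness codes are kept internally
#' (element `codes_complete`) so phenotypes can be generated from true
#' genotypes.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] (unoriented) with per-sample design
#'   factors in `$samples`, plus elements `codes_complete` and
#'   `line_freq` (SNP x line B-allele frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(derive_seed(cfg$seed, "genotypes"))
  design <- .sim_design(cfg)

  chrom <- sort(rep(cfg$chroms, length.out = cfg$n_snps))
  chrom <- chrom[order(match(chrom, cfg$chroms))]
  pos <- integer(cfg$n_snps)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(cfg$chrom_length - 1L, length(idx))) + 1L
  }
  pairs <- matrix(c("A", "C", "A", "G", "A", "T", "C", "G", "C", "T", "G", "T"),
                  ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), cfg$n_snps, replace = TRUE)
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(cfg$n_snps)),
                     chrom = chrom, pos = pos,
                     allele_a = pairs[pick, 1], allele_b = pairs[pick, 2])

  line_freq <- matrix(NA_real_, cfg$n_snps, cfg$n_lines,
                      dimnames = list(snps$snp_id, NULL))
  codes <- matrix(NA_real_, cfg$n_hens, cfg$n_snps,
                  dimnames = list(design$samples$hen_id, snps$snp_id))
  for (l in seq_len(cfg$n_lines)) {
    rng <- cfg$line_maf_ranges[[l]]
    line_freq[, l] <- runif(cfg$n_snps, rng[1], rng[2])
    rows <- which(design$samples$line == l)
    codes[rows, ] <- matrix(
      rbinom(length(rows) * cfg$n_snps, 2,
             rep(line_freq[, l], each = length(rows))),
      nrow = length(rows))
  }
  complete <- codes
  if (cfg$missing_rate > 0)
    codes[runif(length(codes)) < cfg$missing_rate] <- NA_real_
  g <- genotype_matrix(codes, snps, design$samples, oriented = FALSE)
  g$codes_complete <- complete
  g$line_freq <- line_freq
  g
}

#' Simulate a phenotype with planted QTL and full truth bookkeeping
#'
#' Trait value per hen = overall mean + generation effect + line effect +
#' random sire effect (N(0, sire_sd^2), nested within line) + sum over
#' planted QTL of the genotype-coded effect (0 copies of the B allele:
#' `+a`; heterozygote: `d`; 2 copies: `-a`) + N(0, resid_sd^2) residual.
#' QTL genotypes come from the complete (pre-missingness) codes. The
#' returned truth record stores every realized component, so trait values
#' can be reconstructed exactly when `resid_sd = 0`.
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return `list(pheno = data.frame, truth = synthetic_truth)`.
#' @export
simulate_phenotypes <- function(g, config) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_qtl > ncol(g$codes))
    stop("n_qtl exceeds the number of simulated SNPs")
  set.seed(derive_seed(cfg$seed, paste0("phenotypes:", cfg$trait)))
  complete <- g$codes_complete %||% g$codes
  if (anyNA(complete))
    stop("QTL genotypes contain missing values; impute before simulating")
  design <- g$samples

  freq_b <- colMeans(complete) / 2
  maf <- pmin(freq_b, 1 - freq_b)
  eligible <- which(maf >= cfg$qtl_min_maf)
  if (cfg$n_qtl > 0 && length(eligible) < cfg$n_qtl)
    stop("fewer than n_qtl SNPs have overall MAF >= qtl_min_maf; ",
         "lower 'qtl_min_maf'")
  qtl_idx <- if (cfg$n_qtl > 0) sort(sample(eligible, cfg$n_qtl)) else integer()
  qtl_a <- rep(cfg$qtl_a, length.out = cfg$n_qtl)
  qtl_d <- rep(cfg$qtl_d, length.out = cfg$n_qtl)

  sire_levels <- sort(unique(design$sire_id))
  sire_effects <- setNames(rnorm(length(sire_levels), 0, cfg$sire_sd),
                           sire_levels)
  qtl_codes <- complete[, qtl_idx, drop = FALSE]
  # genotype-coded QTL value: 0 -> +a, 1 -> d, 2 -> -a
  qtl_value <- function(code, a, d) ifelse(code == 0, a, ifelse(code == 1, d, -a))
  qtl_sum <- rep(0, nrow(complete))
  for (j in seq_len(cfg$n_qtl))
    qtl_sum <- qtl_sum + qtl_value(qtl_codes[, j], qtl_a[j], qtl_d[j])

  y <- cfg$mean + cfg$generation_effects[design$generation] +
    cfg$line_effects[design$line] + sire_effects[design$sire_id] +
    qtl_sum + rnorm(nrow(complete), 0, cfg$resid_sd)

  pheno <- design
  pheno[[cfg$trait]] <- as.numeric(y)
  truth <- structure(list(
    trait = cfg$trait, mean = cfg$mean,
    qtl = data.frame(snp_id = colnames(complete)[qtl_idx],
                     a = qtl_a, d = qtl_d),
    qtl_codes = qtl_codes,
    line_effects = cfg$line_effects,
    generation_effects = cfg$generation_effects,
    sire_effects = sire_effects,
    sire_sd = cfg$sire_sd, resid_sd = cfg$resid_sd),
    class = "synthetic_truth")
  list(pheno = pheno, truth = truth)
}

#' Reconstruct noise-free trait values from a truth record
#'
#' Deterministic part of the generative model (everything except the
#' residual draw); with `resid_sd = 0` this reproduces simulated trait
#' values exactly.
#'
#' @param truth a `synthetic_truth` from [simulate_phenotypes()].
#' @param design data.frame with `line`, `generation`, `sire_id` rows
#'   matching the truth's QTL code matrix.
#' @return Numeric vector of expected trait values.
#' @export
truth_expected_values <- function(truth, design) {
  qtl_sum <- rep(0, nrow(design))
  if (nrow(truth$qtl) > 0) {
    for (j in seq_len(nrow(truth$qtl))) {
      code <- truth$qtl_codes[, j]
      qtl_sum <- qtl_sum + ifelse(code == 0, truth$qtl$a[j],
                                  ifelse(code == 1, truth$qtl$d[j],
                                         -truth$qtl$a[j]))
    }
  }
  unname(truth$mean + truth$generation_effects[design$generation] +
           truth$line_effects[design$line] +
           truth$sire_effects[design$sire_id] + qtl_sum)
}

#' Simulate gene models and gene sets around planted QTL
#'
#' Places non-overlapping protein-coding gene intervals so that a
#' configurable fraction of the given QTL SNPs have a gene within
#' `window_bp`, while all remaining genes stay clear of every QTL window.
#' Genes are partitioned into labelled sets, with the first term
#' collecting all QTL-adjacent genes (the planted enriched term).
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the [sim_config()] used for the genotypes.
#' @param qtl_snp_ids character vector of planted QTL SNP ids (from one or
#'   more truth records).
#' @param fraction_near fraction of QTL SNPs that get an adjacent gene.
#' @param n_genes,n_sets total genes and gene-set terms.
#' @param window_bp adjacency window in bp (default 5000).
#' @return `list(genes = GRanges, sets = named list, enriched_term)`.
#' @export
simulate_gene_annotation <- function(g, config, qtl_snp_ids = character(),
                                     fraction_near = 1, n_genes = 40,
                                     n_sets = 10, window_bp = 5000) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  if (n_sets > n_genes) stop("n_sets cannot exceed n_genes")
  qtl <- g$snps[g$snps$snp_id %in% qtl_snp_ids, , drop = FALSE]
  n_near <- round(fraction_near * nrow(qtl))
  near_idx <- if (nrow(qtl)) seq_len(n_near) else integer()
  if (n_genes < n_near) stop("n_genes too small for the requested fraction_near")

  chrom <- character(); start <- integer(); end <- integer()
  place_ok <- function(ch, s, e, avoid_qtl) {
    if (s < 1 || e > config$chrom_length) return(FALSE)
    same <- which(chrom == ch)
    if (any(start[same] <= e & end[same] >= s)) return(FALSE)  # overlap
    if (avoid_qtl) {
      q <- qtl[qtl$chrom == ch, , drop = FALSE]
      if (nrow(q) && any(q$pos >= s - window_bp & q$pos <= e + window_bp))
        return(FALSE)
    }
    TRUE
  }
  # genes adjacent to the selected QTL SNPs (gene body covers the SNP)
  for (i in near_idx) {
    placed <- FALSE
    for (try in 1:200) {
      len <- sample(3000:8000, 1)
      s <- qtl$pos[i] - sample.int(len, 1) + 1L
      e <- s + len - 1L
      if (place_ok(qtl$chrom[i], s, e, avoid_qtl = FALSE)) {
        chrom <- c(chrom, qtl$chrom[i]); start <- c(start, s); end <- c(end, e)
        placed <- TRUE; break
      }
    }
    if (!placed) stop("chromosome too small to place a gene near SNP ",
                      qtl$snp_id[i])
  }
  # background genes, kept clear of every QTL window
  while (length(chrom) < n_genes) {
    placed <- FALSE
    for (try in 1:500) {
      ch <- sample(config$chroms, 1)
      len <- sample(3000:8000, 1)
      s <- sample.int(max(config$chrom_length - len, 1), 1)
      e <- s + len - 1L
      if (place_ok(ch, s, e, avoid_qtl = TRUE)) {
        chrom <- c(chrom, ch); start <- c(start, s); end <- c(end, e)
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop("chromosome lengths too small to place ", n_genes,
           " non-overlapping genes")
  }
  gene_id <- sprintf("GENE%03d", seq_len(n_genes))
  genes <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = sample(c("+", "-"), n_genes, replace = TRUE))
  S4Vectors::mcols(genes)$gene_id <- gene_id
  S4Vectors::mcols(genes)$name <- gene_id
  S4Vectors::mcols(genes)$biotype <- "protein_coding"

  near_genes <- gene_id[seq_along(near_idx)]
  rest <- setdiff(gene_id, near_genes)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  sets[[1]] <- near_genes
  if (n_sets > 1) {
    split_idx <- rep(2:n_sets, length.out = length(rest))
    for (k in 2:n_sets) sets[[k]] <- rest[split_idx == k]
  } else {
    sets[[1]] <- c(sets[[1]], rest)
  }
  # a term must not be empty: top up from the background genes if needed
  empty <- lengths(sets) == 0
  if (any(empty) && length(rest)) {
    donors <- rep(rest, length.out = sum(empty))
    sets[empty] <- as.list(donors)
  }
  list(genes = genes, sets = sets, enriched_term = names(sets)[1])
}

#' Write gene models to GFF3
#' @param genes GRanges with `gene_id`, `name`, `biotype` metadata.
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- genes
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$gene_id
  S4Vectors::mcols(gr)$source <- "henbone"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a truth record to JSON
#' @param truth a `synthetic_truth` (or list of them, one per trait).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (inherits(truth, "synthetic_truth")) truth <- list(truth)
  ser <- lapply(truth, function(tr) {
    list(trait = tr$trait, mean = tr$mean, qtl = tr$qtl,
         qtl_codes = tr$qtl_codes, line_effects = tr$line_effects,
         generation_effects = tr$generation_effects,
         sire_effects = as.list(tr$sire_effects),
         sire_sd = tr$sire_sd, resid_sd = tr$resid_sd)
  })
  names(ser) <- vapply(ser, `[[`, "", "trait")
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a truth record written by [write_truth()]
#' @param path JSON file.
#' @return Named list of `synthetic_truth` records, one per trait.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(tr) {
    structure(list(trait = tr$trait, mean = tr$mean,
                   qtl = as.data.frame(tr$qtl),
                   qtl_codes = as.matrix(tr$qtl_codes),
                   line_effects = unlist(tr$line_effects),
                   generation_effects = unlist(tr$generation_effects),
                   sire_effects = unlist(tr$sire_effects),
                   sire_sd = tr$sire_sd, resid_sd = tr$resid_sd),
              class = "synthetic_truth")
  })
}
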