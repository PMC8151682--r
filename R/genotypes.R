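#' Construct a genotype matrix object
#'
#' Container for biallelic SNP genotypes coded as copies of the B allele
#' (0 = AA, 1 = AB, 2 = BB, `NA` = missing), with per-SNP metadata and
#' optional per-sample design factors. After [orient_minor_allele()] the
#' codes count copies of the effect (minor) allele.
#'
#' @param codes integer matrix, samples in rows and SNPs in columns;
#'   dimnames give sample ids and SNP ids.
#' @param snps data.frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b` and, once oriented, `ea`, `oa`, `ea_freq`.
#' @param samples optional data.frame with one row per sample (`hen_id`
#'   and, when known, `line`, `generation`, `sire_id`).
#' @param oriented logical; `TRUE` once codes count effect-allele copies.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, snps, samples = NULL, oriented = FALSE) {
  codes <- as.matrix(codes)
  if (!is.numeric(codes)) stop("genotype codes must be numeric (0/1/2/NA)")
  bad <- codes[!is.na(codes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (nrow(snps) != ncol(codes))
    stop("snps metadata rows must match the number of genotype columns")
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("snps metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  snps$chrom <- as.character(snps$chrom)
  for (col in c("ea", "oa")) if (is.null(snps[[col]])) snps[[col]] <- NA_character_
  if (is.null(snps$ea_freq)) snps$ea_freq <- NA_real_
  colnames(codes) <- snps$snp_id
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("sample%04d", seq_len(nrow(codes)))
  if (is.null(samples)) samples <- data.frame(hen_id = rownames(codes))
  if (nrow(samples) != nrow(codes))
    stop("samples metadata rows must match the number of genotype rows")
  structure(list(codes = codes, snps = snps, samples = samples,
                 oriented = isTRUE(oriented)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%s; %.2f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              if (x$oriented) "minor-allele oriented" else "unoriented",
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Read genotypes from VCF or a TSV code matrix
#'
#' VCF input is parsed with \pkg{vcfR}; only biallelic SNP records with a
#' GT field are kept, and skipped multi-allelic or non-SNP records are
#' counted in a warning. TSV input has a header row of SNP ids, one sample
#' per row (first column = sample id) and cells 0/1/2/NA; SNP metadata is
#' then taken from optional `#snp` header lines or defaults.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()] with `oriented = FALSE`; codes count ALT
#'   (allele B) copies.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") .read_genotypes_vcf(path) else .read_genotypes_tsv(path)
}

.read_genotypes_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    warning(sprintf("skipped %d non-biallelic or non-SNP record(s)", n_skip))
    vcf <- vcf[is_snp, ]
    fix <- fix[is_snp, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  lut <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2)
  code <- t(matrix(lut[gt], nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt)))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  snps <- data.frame(snp_id = ids, chrom = as.character(fix$CHROM),
                     pos = as.integer(fix$POS),
                     allele_a = fix$REF, allele_b = fix$ALT)
  genotype_matrix(code, snps, oriented = FALSE)
}

.read_genotypes_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
  meta_idx <- grepl("^#", tab[[1]])
  meta <- tab[meta_idx, , drop = FALSE]
  tab <- tab[!meta_idx, , drop = FALSE]
  codes <- as.matrix(tab[, -1, drop = FALSE])
  mode(codes) <- "numeric"
  rownames(codes) <- tab[[1]]
  snp_id <- colnames(codes)
  if (nrow(meta) >= 4) {
    snps <- data.frame(snp_id = snp_id,
                       chrom = as.character(unlist(meta[1, -1])),
                       pos = as.integer(unlist(meta[2, -1])),
                       allele_a = as.character(unlist(meta[3, -1])),
                       allele_b = as.character(unlist(meta[4, -1])))
  } else {
    snps <- data.frame(snp_id = snp_id, chrom = NA_character_,
                       pos = NA_integer_, allele_a = "A", allele_b = "B")
  }
  genotype_matrix(codes, snps, oriented = FALSE)
}

#' Write genotypes to VCF or TSV
#'
#' The VCF writer emits a minimal plain-text VCFv4.2 body (GT field only)
#' so fixtures stay uncompressed and diffable; the TSV writer mirrors the
#' layout read by [read_genotypes()], with four `#`-prefixed metadata rows
#' (chrom, pos, alleles) above the sample rows.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    gt <- matrix("./.", nrow = ncol(g$codes), ncol = nrow(g$codes))
    for (v in 0:2) gt[t(g$codes) == v] <- c("0/0", "0/1", "1/1")[v + 1]
    body <- paste(g$snps$chrom, g$snps$pos, g$snps$snp_id, g$snps$allele_a,
                  g$snps$allele_b, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    header <- c("##fileformat=VCFv4.2",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", rownames(g$codes)), collapse = "\t"))
    writeLines(c(header, body), path)
  } else {
    meta <- rbind(`#chrom` = g$snps$chrom, `#pos` = g$snps$pos,
                  `#allele_a` = g$snps$allele_a, `#allele_b` = g$snps$allele_b)
    lines <- c(paste(c("sample_id", g$snps$snp_id), collapse = "\t"),
               paste(rownames(meta),
                     apply(meta, 1, paste, collapse = "\t"), sep = "\t"),
               paste(rownames(g$codes),
                     apply(g$codes, 1, paste, collapse = "\t"), sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Apply call-rate and autosome quality-control filters
#'
#' Filters in a fixed, logged order: non-autosomal SNPs are removed first,
#' then SNPs below the SNP call-rate threshold, then animals below the
#' animal call-rate threshold. The step-by-step report is attached as
#' attribute `"qc_report"` (see [qc_report()]).
#'
#' @param g a [genotype_matrix()].
#' @param snp_call_rate minimum fraction of non-missing calls per SNP
#'   (default 0.99).
#' @param animal_call_rate minimum fraction of non-missing calls per
#'   animal (default 0.95).
#' @param autosomes chromosome labels to keep (default `"1"`..`"28"`).
#' @return The filtered `genotype_matrix`.
#' @export
apply_qc <- function(g, snp_call_rate = 0.99, animal_call_rate = 0.95,
                     autosomes = as.character(1:28)) {
  stopifnot(inherits(g, "genotype_matrix"))
  report <- data.frame(step = character(), unit = character(),
                       n_in = integer(), n_removed = integer(),
                       n_retained = integer())
  log_step <- function(step, unit, n_in, n_rm) {
    rbind(report, data.frame(step = step, unit = unit, n_in = n_in,
                             n_removed = n_rm, n_retained = n_in - n_rm))
  }
  keep_snp <- g$snps$chrom %in% autosomes
  report <- log_step("autosome", "snp", ncol(g$codes), sum(!keep_snp))
  codes <- g$codes[, keep_snp, drop = FALSE]
  snps <- g$snps[keep_snp, , drop = FALSE]

  snp_cr <- colMeans(!is.na(codes))
  keep_snp <- snp_cr >= snp_call_rate
  report <- log_step("snp_call_rate", "snp", ncol(codes), sum(!keep_snp))
  codes <- codes[, keep_snp, drop = FALSE]
  snps <- snps[keep_snp, , drop = FALSE]

  ani_cr <- if (ncol(codes)) rowMeans(!is.na(codes)) else rep(1, nrow(codes))
  keep_ani <- ani_cr >= animal_call_rate
  report <- log_step("animal_call_rate", "animal", nrow(codes), sum(!keep_ani))
  codes <- codes[keep_ani, , drop = FALSE]
  samples <- g$samples[keep_ani, , drop = FALSE]

  if (ncol(codes) == 0L || nrow(codes) == 0L)
    stop("QC removed all SNPs or all animals; nothing left to analyse")
  out <- genotype_matrix(codes, snps, samples, oriented = g$oriented)
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC step report attached by [apply_qc()]
#' @param g a `genotype_matrix` returned by [apply_qc()].
#' @return data.frame with columns step, unit, n_in, n_removed, n_retained.
#' @export
qc_report <- function(g) attr(g, "qc_report")

#' Effect-allele frequency from genotype counts
#'
#' Frequency of the B allele among non-missing calls,
#' `(n_AB + 2 n_BB) / (2 N)`. Applied after minor-allele orientation this
#' is the effect-allele (minor-allele) frequency in `[0, 0.5]`.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectorised).
#' @return Numeric allele frequency in `[0, 1]`.
#' @export
ea_freq_from_counts <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  ifelse(n > 0, (n_ab + 2 * n_bb) / (2 * n), NA_real_)
}

#' Orient genotype codes to the minor (effect) allele
#'
#' Per SNP, the allele with frequency at most 0.5 among non-missing calls
#' becomes the effect allele (EA); codes at SNPs whose B allele is the
#' major allele are flipped (`c -> 2 - c`). A tie at exactly 0.5 is broken
#' towards the lexicographically smaller allele string, so the result does
#' not depend on input allele order. Monomorphic SNPs are retained with
#' `ea_freq = 0` and a warning.
#'
#' @param g a [genotype_matrix()].
#' @return The oriented `genotype_matrix` with `ea`, `oa` and `ea_freq`
#'   filled in and `oriented = TRUE`.
#' @export
orient_minor_allele <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  snps <- g$snps
  freq_b <- colMeans(codes, na.rm = TRUE) / 2
  freq_b[is.nan(freq_b)] <- 0
  mono <- freq_b %in% c(0, 1)
  flip <- freq_b > 0.5
  tie <- abs(freq_b - 0.5) < 1e-12
  # at a tie the effect allele is the lexicographically smaller string
  flip[tie] <- snps$allele_a[tie] < snps$allele_b[tie]
  codes[, flip] <- 2 - codes[, flip, drop = FALSE]
  snps$ea <- ifelse(flip, snps$allele_a, snps$allele_b)
  snps$oa <- ifelse(flip, snps$allele_b, snps$allele_a)
  snps$ea_freq <- colMeans(codes, na.rm = TRUE) / 2
  if (any(mono))
    warning(sprintf("%d monomorphic SNP(s) retained with ea_freq 0", sum(mono)))
  out <- genotype_matrix(codes, snps, g$samples, oriented = TRUE)
  attr(out, "qc_report") <- attr(g, "qc_report")
  out
}

#' Naive within-line frequency imputation of missing genotypes
#'
#' Stand-in for reference-panel imputation: each missing call is drawn
#' from the SNP's empirical genotype distribution within the animal's
#' layer line (falling back to the overall distribution, with a warning,
#' when a SNP has no call in a line). Deterministic given the seed.
#'
#' @param g a [genotype_matrix()].
#' @param lines per-sample line labels; defaults to `g$samples$line`, or a
#'   single pooled group when no line information is available.
#' @param seed integer seed.
#' @return A `genotype_matrix` with no missing codes.
#' @export
naive_impute <- function(g, lines = NULL, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  lines <- lines %||% g$samples$line %||% rep("all", nrow(g$codes))
  if (length(lines) != nrow(g$codes))
    stop("'lines' must have one entry per sample")
  codes <- g$codes
  set.seed(seed)
  n_fallback <- 0L
  for (j in which(colSums(is.na(codes)) > 0)) {
    x <- codes[, j]
    overall <- tabulate(x + 1L, nbins = 3L)
    if (sum(overall) == 0L)
      stop("SNP ", g$snps$snp_id[j], " has no non-missing call; run QC first")
    for (ln in unique(lines[is.na(x)])) {
      in_line <- lines == ln
      cnt <- tabulate(x[in_line] + 1L, nbins = 3L)
      if (sum(cnt) == 0L) {
        cnt <- overall
        n_fallback <- n_fallback + 1L
      }
      idx <- which(in_line & is.na(x))
      codes[idx, j] <- sample(0:2, length(idx), replace = TRUE,
                              prob = cnt / sum(cnt))
    }
  }
  if (n_fallback > 0)
    warning(sprintf(
      "%d SNP-line cell(s) had no call in-line; used overall frequencies",
      n_fallback))
  out <- genotype_matrix(codes, g$snps, g$samples, oriented = g$oriented)
  attr(out, "qc_report") <- attr(g, "qc_report")
  out
}

#' Read a phenotype table
#'
#' CSV with columns `hen_id`, `generation`, `line`, `sire_id` and one or
#' more trait columns (e.g. `Tib_BBS` in N, `Tib_BMD` in g/cm2).
#'
#' @param path CSV file.
#' @return data.frame with factor columns for the design variables.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hen_id", "generation", "line", "sire_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$hen_id)) stop("duplicated hen_id in phenotype table")
  tab
}

#' Write a phenotype table to CSV
#' @param pheno phenotype data.frame.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
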