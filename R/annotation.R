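#' Read protein-coding gene models from GFF3
#'
#' Imports gene records with \pkg{rtracklayer} and keeps only those of
#' the requested biotype. Records carry `gene_id`, `name` and `biotype`
#' metadata; coordinates are 1-based and endpoint-inclusive, as in GFF3.
#'
#' @param path GFF3 file.
#' @param biotype biotype to retain (default `"protein_coding"`).
#' @return GRanges of gene models.
#' @export
read_gff3 <- function(path, biotype = "protein_coding") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type)) gr <- gr[as.character(mc$type) == "gene"]
  mc <- S4Vectors::mcols(gr)
  bt <- mc$biotype %||% mc$gene_biotype
  if (!is.null(bt)) gr <- gr[!is.na(bt) & as.character(bt) == biotype]
  mc <- S4Vectors::mcols(gr)
  gene_id <- as.character(mc$gene_id %||% mc$ID %||% mc$Name)
  if (is.null(gene_id) || anyNA(gene_id))
    gene_id <- paste0("gene", seq_along(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = gene_id,
    name = as.character(mc$name %||% mc$Name %||% gene_id),
    biotype = biotype)
  gr
}

#' Map SNPs to genes within a symmetric window
#'
#' A SNP hits a gene when its position lies in
#' `[gene_start - window_bp, gene_end + window_bp]` (endpoints
#' inclusive). Location is `intragenic` when the SNP falls inside the
#' gene body; otherwise it is `upstream` when the SNP lies on the gene's
#' 5' side with respect to strand and `downstream` otherwise (unstranded
#' genes are treated as `+`). Distance is 0 for intragenic hits, else the
#' bp gap to the nearest gene boundary. A SNP may hit several genes and a
#' gene several SNPs; output is deduplicated per (snp, gene).
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (a
#'   [genotype_matrix()] is also accepted).
#' @param genes GRanges from [read_gff3()] /
#'   [simulate_gene_annotation()].
#' @param window_bp window size in bp (default 5000).
#' @return data.frame with columns snp_id, gene_id, name, chrom,
#'   location, distance.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 5000) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  if (inherits(snps, "genotype_matrix")) snps <- snps$snps
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  if (nrow(snps) == 0L || length(genes) == 0L)
    return(data.frame(snp_id = character(), gene_id = character(),
                      name = character(), chrom = character(),
                      location = character(), distance = integer()))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = snps$pos, width = 1))
  expanded <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(genes) - window_bp),
      end = GenomicRanges::end(genes) + window_bp))
  # seqlevels may legitimately differ (chromosomes with SNPs but no genes)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(snp_gr, expanded, ignore.strand = TRUE))
  si <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  pos <- snps$pos[si]
  gstart <- GenomicRanges::start(genes)[gi]
  gend <- GenomicRanges::end(genes)[gi]
  strand <- as.character(GenomicRanges::strand(genes))[gi]
  strand[strand == "*"] <- "+"
  inside <- pos >= gstart & pos <= gend
  left <- pos < gstart
  distance <- ifelse(inside, 0L, ifelse(left, gstart - pos, pos - gend))
  location <- ifelse(inside, "intragenic",
                     ifelse((left & strand == "+") | (!left & strand == "-"),
                            "upstream", "downstream"))
  out <- data.frame(snp_id = snps$snp_id[si],
                    gene_id = S4Vectors::mcols(genes)$gene_id[gi],
                    name = S4Vectors::mcols(genes)$name[gi],
                    chrom = as.character(snps$chrom[si]),
                    location = location, distance = as.integer(distance))
  unique(out)
}

#' Disjoint-region counts for a Venn diagram of gene sets
#'
#' For k named sets, counts the elements falling in each of the
#' `2^k - 1` disjoint membership regions; region counts sum to the size
#' of the union.
#'
#' @param gene_sets named list of character vectors.
#' @return data.frame with columns `region` (member set names joined by
#'   `&`) and `count`, ordered by region size then name.
#' @export
venn_counts <- function(gene_sets) {
  if (!length(gene_sets)) stop("empty gene-set list")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop("gene sets must be named")
  gene_sets <- lapply(gene_sets, unique)
  universe <- unique(unlist(gene_sets, use.names = FALSE))
  k <- length(gene_sets)
  membership <- matrix(FALSE, nrow = length(universe), ncol = k,
                       dimnames = list(NULL, names(gene_sets)))
  for (j in seq_len(k)) membership[, j] <- universe %in% gene_sets[[j]]
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(gene_sets)
  region <- apply(combos, 1, function(r)
    paste(names(gene_sets)[as.logical(r)], collapse = "&"))
  count <- apply(combos, 1, function(r)
    sum(apply(membership, 1, function(m) all(m == as.logical(r)))))
  ord <- order(rowSums(combos), region)
  data.frame(region = region[ord], count = as.integer(count[ord]),
             row.names = NULL)
}
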