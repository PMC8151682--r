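#' Read a GMT gene-set collection
#'
#' Tab-delimited GMT: term id, description, then member genes. Lines are
#' validated (a parse error reports the offending line number), sets are
#' parsed with [fgsea::gmtPathways()], duplicate genes within a term are
#' dropped, and the universe defaults to the union of all term genes.
#'
#' @param path GMT file.
#' @param universe optional explicit gene universe (character vector or a
#'   file with one gene id per line), mirroring an "all known genes"
#'   background.
#' @return A `gene_set_collection`: `terms` (named list),
#'   `descriptions` (named character) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf < 3))
    stop("malformed GMT line ", which(nf < 3)[1], ": fewer than 3 fields")
  terms <- lapply(fgsea::gmtPathways(path), unique)
  descriptions <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 2)
  names(descriptions) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  if (is.character(universe) && length(universe) == 1 && file.exists(universe))
    universe <- readLines(universe)
  universe <- unique(universe %||% unlist(terms, use.names = FALSE))
  structure(list(terms = terms, descriptions = descriptions[names(terms)],
                 universe = universe),
            class = "gene_set_collection")
}

#' Write gene sets to GMT
#' @param sets named list of gene id vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (term name reused when
#'   absent).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, universe of %d genes\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation analysis of a gene list
#'
#' For each term, tests whether the query contains more term genes than
#' expected when drawing `n = |query in universe|` genes from the
#' universe: `p_raw = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`. P-values are adjusted across terms by
#' Benjamini-Hochberg (default) or Bonferroni.
#'
#' @param query character vector of gene ids; genes outside the universe
#'   are dropped with a message.
#' @param collection a [read_gmt()] collection (or named list of sets).
#' @param method `"BH"` or `"bonferroni"`.
#' @param alpha significance level for the `significant` flag.
#' @param universe optional override of the collection's universe.
#' @return data.frame sorted by adjusted p-value with columns term_id,
#'   name, k, K, n, N, p_raw, p_adj, significant.
#' @export
enrich <- function(query, collection, method = c("BH", "bonferroni"),
                   alpha = 0.05, universe = NULL) {
  method <- match.arg(method)
  if (!inherits(collection, "gene_set_collection"))
    collection <- structure(list(terms = collection,
                                 descriptions = setNames(names(collection),
                                                         names(collection)),
                                 universe = unique(unlist(collection))),
                            class = "gene_set_collection")
  uni <- unique(universe %||% collection$universe)
  query <- unique(query)
  dropped <- sum(!query %in% uni)
  if (dropped > 0)
    message(dropped, " query gene(s) outside the universe dropped")
  q <- intersect(query, uni)
  if (!length(q)) stop("no query genes left inside the universe")
  N <- length(uni)
  n <- length(q)
  rows <- lapply(names(collection$terms), function(term) {
    genes <- intersect(collection$terms[[term]], uni)
    K <- length(genes)
    k <- length(intersect(q, genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term,
               name = unname(collection$descriptions[term] %||% term),
               k = k, K = K, n = n, N = N, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_raw,
                        method = if (method == "BH") "BH" else "bonferroni")
  out <- out[order(out$p_adj, out$p_raw, out$term_id), , drop = FALSE]
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
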