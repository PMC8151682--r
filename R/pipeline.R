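#' Configuration for the end-to-end pipeline
#'
#' @param genotypes,phenotypes,gff3,gmt input file paths (VCF/TSV
#'   genotypes, phenotype CSV, gene models, gene sets).
#' @param outdir output directory (created if absent).
#' @param traits trait columns to analyse.
#' @param snp_call_rate,animal_call_rate,autosomes QC thresholds, as in
#'   [apply_qc()].
#' @param boruta a [boruta_config()]; its seed is overridden by a seed
#'   derived from `seed`.
#' @param window_bp gene-mapping window (default 5000).
#' @param enrich_method `"BH"` or `"bonferroni"`.
#' @param seed master seed; each stage derives its own seed from it via
#'   [derive_seed()] so stages are independently reproducible.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, phenotypes, gff3, gmt, outdir,
                            traits = c("Tib_BBS", "Tib_BMD"),
                            snp_call_rate = 0.99, animal_call_rate = 0.95,
                            autosomes = as.character(1:28),
                            boruta = boruta_config(), window_bp = 5000,
                            enrich_method = "BH", seed = 1) {
  if (!length(traits)) stop("at least one trait is required")
  structure(list(genotypes = genotypes, phenotypes = phenotypes, gff3 = gff3,
                 gmt = gmt, outdir = outdir, traits = traits,
                 snp_call_rate = snp_call_rate,
                 animal_call_rate = animal_call_rate, autosomes = autosomes,
                 boruta = boruta, window_bp = window_bp,
                 enrich_method = enrich_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

.validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("genotypes", "phenotypes", "gff3", "gmt"))
    if (!file.exists(config[[f]]))
      stop("pipeline input '", f, "' not found: ", config[[f]])
  pheno <- read_phenotypes(config$phenotypes)
  missing_traits <- setdiff(config$traits, names(pheno))
  if (length(missing_traits))
    stop("trait(s) not in phenotype table: ",
         paste(missing_traits, collapse = ", "))
  invisible(pheno)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes qc (read, filter, impute, orient) -> adjust -> select (Boruta
#' per trait) -> annotate -> effects (confirmed SNPs near genes) -> venn
#' -> enrich, writing stage outputs under `config$outdir` and a
#' `manifest.json` with per-stage seeds, row counts and output-file MD5
#' hashes. Re-running with the same config and seed reproduces identical
#' hashes. Any stage failure aborts with the stage name; files of the
#' failed stage are renamed with a `.partial` suffix.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_all <- function(config) {
  pheno <- .validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, paste0(...))
  manifest <- list(package_version = as.character(utils::packageVersion("henbone")),
                   master_seed = config$seed, stages = list())
  stage_files <- character()
  run_stage <- function(name, fun) {
    stage_files <<- character()
    res <- tryCatch(fun(), error = function(e) {
      for (f in stage_files[file.exists(stage_files)])
        file.rename(f, paste0(f, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(name = name), res,
                                  list(outputs = lapply(
                                    stage_files, function(f)
                                      list(file = basename(f),
                                           md5 = unname(tools::md5sum(f))))))
    res
  }
  emit <- function(df, path) {
    stage_files <<- c(stage_files, path)
    .write_tsv(df, path)
  }

  # -- qc: read, filter, impute, orient ------------------------------------
  g <- NULL
  run_stage("qc", function() {
    g0 <- read_genotypes(config$genotypes)
    g1 <- apply_qc(g0, config$snp_call_rate, config$animal_call_rate,
                   config$autosomes)
    lines <- pheno$line[match(rownames(g1$codes), pheno$hen_id)]
    g2 <- suppressWarnings(naive_impute(g1, lines = lines,
                                        seed = derive_seed(config$seed, "impute")))
    g3 <- suppressWarnings(orient_minor_allele(g2))
    emit(qc_report(g3), out("qc_report.tsv"))
    emit(g3$snps, out("snps_qc.tsv"))
    g <<- g3
    list(seed = derive_seed(config$seed, "impute"),
         n_in = ncol(g0$codes), n_out = ncol(g3$codes),
         n_animals = nrow(g3$codes))
  })

  # -- adjust: mixed-model phenotype adjustment per trait ------------------
  fits <- NULL
  run_stage("adjust", function() {
    pheno <- pheno[pheno$hen_id %in% rownames(g$codes), , drop = FALSE]
    fits <<- lapply(config$traits, function(tr)
      suppressWarnings(fit_adjustment_model(pheno, tr)))
    pheno <<- attach_residuals(pheno, fits)
    emit(do.call(rbind, lapply(fits, function(f)
      data.frame(trait = f$trait, mu = f$mu, sire_variance = f$sire_variance,
                 resid_variance = f$resid_variance, n_used = f$n_used))),
      out("adjustment_summary.tsv"))
    emit(pheno, out("phenotypes_adjusted.tsv"))
    list(n_in = nrow(pheno), n_out = nrow(pheno))
  })

  # -- select: Boruta per trait --------------------------------------------
  boruta_results <- list()
  run_stage("select", function() {
    n_confirmed <- integer()
    for (tr in config$traits) {
      bc <- config$boruta
      bc$seed <- derive_seed(config$seed, paste0("select:", tr))
      resp <- pheno[[paste0("resid_", tr)]][match(rownames(g$codes),
                                                  pheno$hen_id)]
      res <- suppressWarnings(boruta_run(g, resp, bc))
      boruta_results[[tr]] <<- res
      tab <- merge(res$statuses, g$snps[c("snp_id", "chrom", "pos")],
                   by = "snp_id", sort = FALSE)
      emit(tab[order(match(tab$snp_id, g$snps$snp_id)), ],
           out("boruta_", tr, ".tsv"))
      n_confirmed[tr] <- length(confirmed_snps(res))
    }
    list(n_in = ncol(g$codes), n_out = sum(n_confirmed),
         confirmed = as.list(n_confirmed))
  })

  # -- annotate: confirmed SNPs to genes within the window -----------------
  genes <- NULL
  gene_hits <- list()
  run_stage("annotate", function() {
    genes <<- read_gff3(config$gff3)
    n_hits <- integer()
    for (tr in config$traits) {
      conf <- confirmed_snps(boruta_results[[tr]])
      hits <- map_snps_to_genes(g$snps[g$snps$snp_id %in% conf, , drop = FALSE],
                                genes, config$window_bp)
      gene_hits[[tr]] <<- hits
      emit(hits, out("gene_hits_", tr, ".tsv"))
      n_hits[tr] <- nrow(hits)
    }
    list(n_in = length(genes), n_out = sum(n_hits))
  })

  # -- effects: SMR + DRM for confirmed SNPs near genes --------------------
  run_stage("effects", function() {
    n_rows <- 0L
    for (tr in config$traits) {
      snp_ids <- unique(gene_hits[[tr]]$snp_id)
      if (!length(snp_ids)) {
        emit(data.frame(), out("effects_smr_", tr, ".tsv"))
        emit(data.frame(), out("effects_drm_", tr, ".tsv"))
        next
      }
      smr <- lapply(snp_ids, function(s)
        suppressWarnings(fit_smr(g, pheno, s, tr)))
      drm <- lapply(snp_ids, function(s)
        suppressWarnings(fit_drm(g, pheno, s, tr)))
      rep <- effects_report(smr, drm)
      emit(rep$smr, out("effects_smr_", tr, ".tsv"))
      emit(rep$drm, out("effects_drm_", tr, ".tsv"))
      n_rows <- n_rows + nrow(rep$smr)
    }
    list(n_in = sum(vapply(gene_hits, nrow, 0L)), n_out = n_rows)
  })

  # -- venn: overlap of per-trait gene lists -------------------------------
  run_stage("venn", function() {
    sets <- lapply(gene_hits, function(h) unique(h$gene_id))
    vc <- venn_counts(sets)
    emit(vc, out("venn_counts.tsv"))
    list(n_in = length(sets), n_out = nrow(vc))
  })

  # -- enrich: over-representation per trait -------------------------------
  run_stage("enrich", function() {
    collection <- read_gmt(config$gmt)
    n_sig <- 0L
    for (tr in config$traits) {
      q <- unique(gene_hits[[tr]]$gene_id)
      tab <- if (length(q)) {
        suppressMessages(enrich(q, collection, method = config$enrich_method))
      } else data.frame()
      emit(tab, out("enrichment_", tr, ".tsv"))
      if (nrow(tab)) n_sig <- n_sig + sum(tab$significant)
    }
    list(n_in = length(collection$terms), n_out = n_sig)
  })

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a small synthetic demonstration dataset
#'
#' Simulates a complete input bundle at desk scale — by default 524 hens
#' from four lines and two generations, 2000 SNPs on autosomes 1-28,
#' five planted QTL per trait, 40 genes and 10 gene sets — and writes
#' genotypes (plain-text VCF), phenotypes (CSV, two traits on the BBS and
#' BMD scales), gene models (GFF3), gene sets (GMT) and the truth record
#' (JSON) under `outdir`.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param n_hens,n_snps,n_qtl,n_genes,n_sets,n_sires sizes.
#' @return List with the file paths, the per-trait truths and the
#'   [pipeline_config()] ready for [run_all()].
#' @export
demo_fixture <- function(outdir, seed = 1, n_hens = 524, n_snps = 2000,
                         n_qtl = 5, n_genes = 40, n_sets = 10,
                         n_sires = 145) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, mode = 2) != 0) stop("outdir not writable: ", outdir)
  cfg_bbs <- sim_config(n_hens = n_hens, n_snps = n_snps, n_qtl = n_qtl,
                        n_sires = n_sires,
                        qtl_a = 12, qtl_d = 4, mean = 150,
                        line_effects = c(0, 15, -10, 5),
                        generation_effects = c(0, 8),
                        sire_sd = 6, resid_sd = 25,
                        trait = "Tib_BBS", seed = derive_seed(seed, "bbs"))
  cfg_bmd <- sim_config(n_hens = n_hens, n_snps = n_snps, n_qtl = n_qtl,
                        n_sires = n_sires,
                        qtl_a = 0.012, qtl_d = 0.004, mean = 0.25,
                        line_effects = c(0, 0.02, -0.015, 0.01),
                        generation_effects = c(0, 0.01),
                        sire_sd = 0.008, resid_sd = 0.025,
                        trait = "Tib_BMD", seed = derive_seed(seed, "bmd"))
  g <- simulate_genotypes(cfg_bbs)
  sim_bbs <- simulate_phenotypes(g, cfg_bbs)
  cfg_bmd$seed <- derive_seed(seed, "bmd")
  sim_bmd <- simulate_phenotypes(g, cfg_bmd)
  pheno <- sim_bbs$pheno
  pheno$Tib_BMD <- sim_bmd$pheno$Tib_BMD
  qtl_ids <- unique(c(sim_bbs$truth$qtl$snp_id, sim_bmd$truth$qtl$snp_id))
  ann <- simulate_gene_annotation(g, cfg_bbs, qtl_snp_ids = qtl_ids,
                                  fraction_near = 1, n_genes = n_genes,
                                  n_sets = n_sets)
  paths <- list(genotypes = file.path(outdir, "genotypes.vcf"),
                phenotypes = file.path(outdir, "phenotypes.csv"),
                gff3 = file.path(outdir, "genes.gff3"),
                gmt = file.path(outdir, "genesets.gmt"),
                truth = file.path(outdir, "truth.json"))
  write_genotypes(g, paths$genotypes, format = "vcf")
  write_phenotypes(pheno, paths$phenotypes)
  write_gff3(ann$genes, paths$gff3)
  write_gmt(ann$sets, paths$gmt)
  write_truth(list(sim_bbs$truth, sim_bmd$truth), paths$truth)
  config <- pipeline_config(genotypes = paths$genotypes,
                            phenotypes = paths$phenotypes,
                            gff3 = paths$gff3, gmt = paths$gmt,
                            outdir = file.path(outdir, "results"),
                            traits = c("Tib_BBS", "Tib_BMD"),
                            seed = seed)
  list(paths = paths, config = config,
       truth = list(Tib_BBS = sim_bbs$truth, Tib_BMD = sim_bmd$truth),
       enriched_term = ann$enriched_term)
}
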