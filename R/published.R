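#' Published candidate-locus genotypic values
#'
#' Least-squares means (with SEs) of the AA, AB and BB genotype classes
#' reported for 19 SNP-trait combinations at 17 candidate loci in a
#' four-line laying-hen population (bone breaking strength in N, bone
#' mineral density in g/cm2). AA is the homozygote of the other (major)
#' allele and BB the homozygote of the effect (minor) allele. These
#' printed estimates are the worked-example input for the
#' [additive_dominance()] contrast arithmetic.
#'
#' @return data.frame with columns snp_id, trait, gene, lsm_AA..se_BB.
#' @export
published_candidate_lsm <- function() {
  read.delim(system.file("extdata", "candidate_snp_lsm.tsv",
                         package = "henbone"),
             stringsAsFactors = FALSE)
}

#' Published candidate-locus genotype counts and allele information
#'
#' Genotype counts, effect/other alleles and the published effect-allele
#' (minor-allele) frequency for the 17 candidate loci; the worked-example
#' input for [ea_freq_from_counts()].
#'
#' @return data.frame with columns snp_id, trait, location, chrom, pos,
#'   genotypes, n_AA, n_AB, n_BB, ea, oa, ea_freq, gene.
#' @export
published_candidate_info <- function() {
  read.delim(system.file("extdata", "candidate_snp_info.tsv",
                         package = "henbone"),
             stringsAsFactors = FALSE,
             colClasses = c(ea_freq = "numeric"))
}

#' Additive/dominance decomposition of the published genotypic values
#'
#' Applies [additive_dominance()] to every row of
#' [published_candidate_lsm()].
#'
#' @return The LSM table with columns `a` and `d` appended.
#' @export
candidate_effect_contrasts <- function() {
  tab <- published_candidate_lsm()
  cbind(tab, additive_dominance(tab$lsm_AA, tab$lsm_AB, tab$lsm_BB))
}
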