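## Variant retention cascade producing the "core variation" set:
## biallelic SNPs with MAF and missing-rate thresholds, a minimum count of
## alt-homozygous carriers, and an InDel length cap.

#' Per-site summary statistics
#'
#' MAF is computed over non-missing alleles only (the VCFtools/PLINK
#' convention); `n_hom_alt` counts accessions homozygous for the alternate
#' allele (dosage 2).
#'
#' @param gt a [genotype_matrix()].
#' @return data.frame with one row per site: `chrom`, `pos`, `variant_class`,
#'   `indel_length`, `multiallelic`, `maf`, `missing_rate`, `n_hom_alt`.
#' @export
site_stats <- function(gt) {
  stopifnot(inherits(gt, "genotype_matrix"))
  g <- gt$geno
  n_samp <- ncol(g)
  n_miss <- rowSums(is.na(g))
  n_obs_alleles <- 2L * (n_samp - n_miss)
  j <- rowSums(g, na.rm = TRUE)
  af <- ifelse(n_obs_alleles > 0, j / n_obs_alleles, NA_real_)
  data.frame(
    chrom = gt$chrom, pos = gt$pos,
    variant_class = gt$variant_class,
    indel_length = gt$indel_length,
    multiallelic = gt$multiallelic,
    maf = pmin(af, 1 - af),
    missing_rate = n_miss / n_samp,
    n_hom_alt = rowSums(g == 2L, na.rm = TRUE))
}

#' Retain biallelic SNPs passing MAF and missing-rate thresholds
#'
#' Keeps sites that are biallelic SNPs with minor allele frequency at least
#' `maf_min` and missing rate at most `missing_max`. Site order is
#' preserved; an empty result is allowed.
#'
#' @param gt a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param missing_max maximum missing genotype fraction (default 0.8).
#' @return The retained `genotype_matrix`.
#' @export
filter_biallelic <- function(gt, maf_min = 0.01, missing_max = 0.8) {
  st <- site_stats(gt)
  keep <- st$variant_class == "SNP" & !st$multiallelic &
    !is.na(st$maf) & st$maf >= maf_min & st$missing_rate <= missing_max
  subset_sites(gt, keep)
}

#' Retain sites carried homozygous by a minimum number of accessions
#'
#' @param gt a [genotype_matrix()].
#' @param min_hom_accessions minimum number of accessions homozygous for the
#'   alternate allele (default 5); 0 is the identity filter.
#' @return The retained `genotype_matrix`.
#' @export
core_variant_filter <- function(gt, min_hom_accessions = 5) {
  st <- site_stats(gt)
  subset_sites(gt, st$n_hom_alt >= min_hom_accessions)
}

#' Cap InDel length, passing SNPs through unchanged
#'
#' @param gt a [genotype_matrix()].
#' @param max_len maximum retained InDel length in bp (default 20).
#' @return The retained `genotype_matrix`.
#' @export
filter_indels <- function(gt, max_len = 20) {
  keep <- gt$variant_class != "InDel" | gt$indel_length <= max_len
  subset_sites(gt, keep)
}
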