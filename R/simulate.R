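## Synthetic three-stage cotton-like populations with ground truth: SNP
## genotypes with planted low-diversity sweep windows, gene content with a
## configurable core/softcore/shell/cloud/singleton composition and planted
## stage-wise frequency shifts, exon-coverage observations and a phenotype
## coupled to one PAV. Every draw is reproducible from the config seed.

#' Simulation configuration
#'
#' Defaults mirror the population the analysis was designed around: group
#' sizes 256/438/929 (landrace / GhImpUSO / GhImpCHN), per-group
#' heterozygosity scaling 1 / 0.35 / 0.31 (the ratio of representative nucleotide-diversity
#' estimates 1.07e-3, 3.74e-4, 3.34e-4), 35% low-depth accessions, a gene
#' catalogue with representative class proportions scaled to 400 genes, and
#' exon-coverage noise Beta(40, 2) for present genes (mean 0.95) vs
#' Beta(2, 40) for absent ones (mean 0.05), placing mass clearly on either
#' side of the 0.8 presence cutoff.
#'
#' @param seed integer RNG seed.
#' @param n_landrace,n_impuso,n_impchn accession counts per stage group.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_snps total SNP count (distributed over chromosomes by length).
#' @param group_diversity named heterozygosity scaling per group
#'   (landrace = 1 reference).
#' @param sweep_windows NULL or data.frame `chrom`, `start`, `end`,
#'   `factor`: inside each window the improved groups' expected
#'   heterozygosity is divided by `factor`.
#' @param missing_rate per-genotype missing probability.
#' @param gene_counts named vector of planted class counts
#'   (`core`, `softcore`, `shell`, `cloud`, `singleton`).
#' @param selected_genes NULL or data.frame with columns `stage`
#'   (`domestication`/`improvement`), `verdict` (`favorable`/`unfavorable`),
#'   `freq_landrace`, `freq_GhImpUSO`, `freq_GhImpCHN`; the stage fold
#'   change implied by the frequencies must be > 2 or < 0.5 as the verdict
#'   requires.
#' @param low_depth_fraction fraction of accessions flagged depth < 5.
#' @param beta_present,beta_absent Beta(a, b) parameters of the covered
#'   exon fraction conditional on true presence/absence.
#' @param phenotype_effect,phenotype_sd effect size and noise SD of the
#'   phenotype coupled to a designated PAV.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_landrace = 256, n_impuso = 438, n_impchn = 929,
                       chrom_lengths = c(A01 = 2e6),
                       n_snps = 2000,
                       group_diversity = c(landrace = 1, GhImpUSO = 0.35,
                                           GhImpCHN = 0.31),
                       sweep_windows = NULL,
                       missing_rate = 0.02,
                       gene_counts = c(core = 247, softcore = 23,
                                       shell = 15, cloud = 48,
                                       singleton = 67),
                       selected_genes = NULL,
                       low_depth_fraction = 0.35,
                       beta_present = c(40, 2),
                       beta_absent = c(2, 40),
                       phenotype_effect = 1.5,
                       phenotype_sd = 0.5) {
  layout <- genome_layout(chrom_lengths)
  if (any(c(n_landrace, n_impuso, n_impchn) < 1))
    stop("group sizes must be positive")
  if (any(gene_counts < 0)) stop("gene class counts must be non-negative")
  groups3 <- c("landrace", "GhImpUSO", "GhImpCHN")
  if (!all(groups3 %in% names(group_diversity)))
    stop("group_diversity must name all three stage groups")
  if (!is.null(sweep_windows)) {
    stopifnot(all(c("chrom", "start", "end", "factor") %in%
                    names(sweep_windows)))
    if (!all(sweep_windows$chrom %in% names(layout)))
      stop("sweep window on unknown chromosome")
    if (any(sweep_windows$end > layout[sweep_windows$chrom]) ||
        any(sweep_windows$start < 0))
      stop("sweep window outside chromosome")
    if (any(sweep_windows$factor < 1))
      stop("sweep diversity reduction factor must be >= 1")
  }
  if (!is.null(selected_genes)) {
    need <- c("stage", "verdict", "freq_landrace", "freq_GhImpUSO",
              "freq_GhImpCHN")
    stopifnot(all(need %in% names(selected_genes)))
    fc <- ifelse(selected_genes$stage == "domestication",
                 selected_genes$freq_landrace / selected_genes$freq_GhImpUSO,
                 selected_genes$freq_GhImpUSO / selected_genes$freq_GhImpCHN)
    ok <- ifelse(selected_genes$verdict == "favorable", fc < 0.5, fc > 2)
    if (!all(ok, na.rm = TRUE) || anyNA(ok))
      stop("planted selected genes must imply stage fold change > 2 ",
           "(unfavorable) or < 0.5 (favorable)")
  }
  mp <- beta_present[1] / sum(beta_present)
  ma <- beta_absent[1] / sum(beta_absent)
  if (mp <= 0.8 || ma >= 0.2)
    stop("Beta parameters must place present mass above 0.8 and absent ",
         "mass below 0.2 in expectation")
  if (low_depth_fraction < 0 || low_depth_fraction >= 1)
    stop("low_depth_fraction must lie in [0, 1)")
  if (phenotype_sd <= 0) stop("phenotype_sd must be positive")
  structure(list(seed = seed, n_landrace = n_landrace, n_impuso = n_impuso,
                 n_impchn = n_impchn, layout = layout, n_snps = n_snps,
                 group_diversity = group_diversity,
                 sweep_windows = sweep_windows,
                 missing_rate = missing_rate, gene_counts = gene_counts,
                 selected_genes = selected_genes,
                 low_depth_fraction = low_depth_fraction,
                 beta_present = beta_present, beta_absent = beta_absent,
                 phenotype_effect = phenotype_effect,
                 phenotype_sd = phenotype_sd),
            class = "sim_config")
}

## deterministic accession registry (no RNG)
.sim_accessions <- function(config) {
  acc <- c(sprintf("L%04d", seq_len(config$n_landrace)),
           sprintf("U%04d", seq_len(config$n_impuso)),
           sprintf("C%04d", seq_len(config$n_impchn)))
  grp <- rep(c("landrace", "GhImpUSO", "GhImpCHN"),
             c(config$n_landrace, config$n_impuso, config$n_impchn))
  setNames(grp, acc)
}

## solve 2p(1-p) = h for the allele frequency on the side of `upper`
.het_to_freq <- function(h, upper) {
  h <- pmin(h, 0.5)
  p <- (1 - sqrt(1 - 2 * h)) / 2
  ifelse(upper, 1 - p, p)
}

#' Simulate SNP genotypes for a three-stage population
#'
#' Sites are drawn independently (no linkage): each site gets an ancestral
#' allele frequency, groups share it up to their heterozygosity scaling,
#' and inside planted sweep windows the improved groups' expected
#' heterozygosity is additionally divided by the window's factor; genotypes
#' are Hardy-Weinberg binomial draws. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list: `genotypes` (a [genotype_matrix()]), `groups` (named
#'   accession -> group vector), `layout`, and `truth` with the planted
#'   sweep regions as a [region_set()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- .sim_accessions(config)
  acc <- names(groups)
  layout <- config$layout
  n_per_chrom <- pmax(round(config$n_snps * layout / sum(layout)), 1L)
  chrom <- rep(names(layout), n_per_chrom)
  pos <- unlist(lapply(names(layout), function(ch)
    sort(sample.int(layout[[ch]], n_per_chrom[[ch]]) - 1L)), use.names = FALSE)
  n_sites <- length(pos)
  p0 <- runif(n_sites, 0.05, 0.95)
  h0 <- 2 * p0 * (1 - p0)
  upper <- p0 > 0.5
  ## per-site sweep factor applied to the improved groups
  sweep_factor <- rep(1, n_sites)
  sw <- config$sweep_windows
  if (!is.null(sw)) for (i in seq_len(nrow(sw))) {
    inw <- chrom == sw$chrom[i] & pos >= sw$start[i] & pos < sw$end[i]
    sweep_factor[inw] <- pmax(sweep_factor[inw], sw$factor[i])
  }
  geno <- matrix(NA_integer_, n_sites, length(acc),
                 dimnames = list(NULL, acc))
  for (g in c("landrace", "GhImpUSO", "GhImpCHN")) {
    scale <- config$group_diversity[[g]]
    if (g != "landrace") scale <- scale / sweep_factor else scale <- rep(scale, n_sites)
    pg <- .het_to_freq(h0 * scale, upper)
    cols <- which(groups == g)
    geno[, cols] <- rbinom(n_sites * length(cols), 2L, pg)
  }
  if (config$missing_rate > 0) {
    miss <- runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }
  gt <- genotype_matrix(geno, chrom = chrom, pos = pos,
                        ref = rep("A", n_sites), alt = rep("T", n_sites))
  sweep_rs <- if (is.null(sw)) region_set(label = "sweep_truth")
              else region_set(sw$chrom, sw$start, sw$end,
                              label = "sweep_truth")
  list(genotypes = gt, groups = groups, layout = layout,
       truth = list(sweep_regions = sweep_rs))
}

## simple gene placement along the genome (no RNG; ids G0001..)
.sim_gene_models <- function(config, n_genes) {
  layout <- config$layout
  per_chrom <- pmax(round(n_genes * layout / sum(layout)), 0L)
  while (sum(per_chrom) < n_genes) per_chrom[1L] <- per_chrom[1L] + 1L
  while (sum(per_chrom) > n_genes) {
    i <- which(per_chrom > 0)[1L]; per_chrom[i] <- per_chrom[i] - 1L
  }
  genes <- NULL; exons <- NULL; gid <- 0L
  for (ch in names(layout)) {
    ng <- per_chrom[[ch]]
    if (ng == 0L) next
    pitch <- floor(layout[[ch]] / ng)
    if (pitch < 1200) stop("chromosome too short for ", ng, " genes")
    for (k in seq_len(ng)) {
      gid <- gid + 1L
      id <- sprintf("G%05d", gid)
      s <- (k - 1L) * pitch + 100L
      ## two exons of 300 bp separated by a 200 bp intron
      ex <- data.frame(gene_id = id, chrom = ch,
                       start = c(s, s + 500L), end = c(s + 300L, s + 800L))
      genes <- rbind(genes, data.frame(
        gene_id = id, chrom = ch, strand = if (k %% 2) "+" else "-",
        source = "reference", start = s, end = s + 800L,
        exonic_length = 600L))
      exons <- rbind(exons, ex)
    }
  }
  gene_models(genes, exons)
}

#' Simulate gene content, exon coverage and the PAV truth table
#'
#' Plants the configured core/softcore/shell/cloud/singleton composition
#' over high-depth accessions (singletons only in low-depth accessions),
#' plus the configured stage-selected genes with per-group presence
#' frequencies; then draws a covered-exon fraction per (accession, gene)
#' from the presence- or absence-conditional Beta distribution.
#'
#' @param config a [sim_config()].
#' @param models optional [gene_models()]; generated to size when NULL.
#' @param coverage draw the exon-coverage table (TRUE) or skip it when only
#'   the truth presence matrix is needed (FALSE).
#' @return list: `gene_models`, `coverage` (data.frame or NULL), `depth`
#'   (accession, mean_depth), `truth_presence` (0/1 gene x accession
#'   matrix), `truth_genes` (gene_id, true_class, stage, verdict,
#'   trajectory, per-group true and realized frequencies), `groups`.
#' @export
simulate_gene_content <- function(config, models = NULL, coverage = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  groups <- .sim_accessions(config)
  acc <- names(groups)
  n_acc <- length(acc)
  n_sel <- if (is.null(config$selected_genes)) 0L
           else nrow(config$selected_genes)
  counts <- config$gene_counts
  n_genes <- sum(counts) + n_sel
  if (is.null(models)) models <- .sim_gene_models(config, n_genes)
  if (nrow(models$genes) < n_genes)
    stop("gene class counts exceed the available gene models")
  gene_ids <- models$genes$gene_id[seq_len(n_genes)]
  n_low <- round(config$low_depth_fraction * n_acc)
  low <- sample(acc, n_low)
  high <- setdiff(acc, low)
  nh <- length(high)
  if (counts[["singleton"]] > 0L && n_low == 0L)
    stop("singleton genes require at least one low-depth accession")
  thr <- class_thresholds()
  soft_min <- ceiling(thr$softcore_min_fraction * nh)
  cloud_max <- max(1L, floor(thr$cloud_max_fraction * nh))
  if (counts[["shell"]] > 0L && soft_min - 1L < cloud_max + 1L)
    stop("panel too small to plant shell genes")
  pres <- matrix(0L, n_genes, n_acc, dimnames = list(gene_ids, acc))
  true_class <- character(n_genes)
  i <- 0L
  plant_high_count <- function(c_high) {
    v <- integer(n_acc); names(v) <- acc
    v[sample(high, c_high)] <- 1L
    ## low-depth accessions follow the same presence frequency
    v[low] <- rbinom(n_low, 1L, c_high / nh)
    v
  }
  for (cls in c("core", "softcore", "shell", "cloud", "singleton")) {
    for (k in seq_len(counts[[cls]])) {
      i <- i + 1L
      true_class[i] <- cls
      pres[i, ] <- switch(cls,
        core = rep(1L, n_acc),
        softcore = plant_high_count(sample(soft_min:(nh - 1L), 1L)),
        shell = plant_high_count(sample((cloud_max + 1L):(soft_min - 1L),
                                        1L)),
        cloud = plant_high_count(sample.int(cloud_max, 1L)),
        singleton = {
          v <- integer(n_acc); names(v) <- acc
          v[sample(low, min(n_low, sample.int(3L, 1L)))] <- 1L
          v
        })
    }
  }
  sel <- config$selected_genes
  sel_rows <- integer(0)
  if (n_sel > 0L) for (k in seq_len(n_sel)) {
    i <- i + 1L
    sel_rows <- c(sel_rows, i)
    true_class[i] <- "selected"
    f <- c(landrace = sel$freq_landrace[k], GhImpUSO = sel$freq_GhImpUSO[k],
           GhImpCHN = sel$freq_GhImpCHN[k])
    pres[i, ] <- rbinom(n_acc, 1L, f[groups])
  }
  ## truth table: intended frequencies, verdicts and strict-chain trajectory
  traj <- function(fL, fU, fC) {
    if (fC > fU && fU > fL) "favorable_gain"
    else if (fU > fL && fC < fU) "favorable_loss"
    else if (fL > fU && fC > fU) "unfavorable_gain"
    else if (fC < fU && fU < fL) "unfavorable_loss"
    else "none"
  }
  truth <- data.frame(gene_id = gene_ids, true_class = true_class,
                      stage = NA_character_, verdict = NA_character_,
                      trajectory = NA_character_,
                      true_freq_landrace = NA_real_,
                      true_freq_GhImpUSO = NA_real_,
                      true_freq_GhImpCHN = NA_real_)
  if (n_sel > 0L) {
    truth$stage[sel_rows] <- sel$stage
    truth$verdict[sel_rows] <- sel$verdict
    truth$true_freq_landrace[sel_rows] <- sel$freq_landrace
    truth$true_freq_GhImpUSO[sel_rows] <- sel$freq_GhImpUSO
    truth$true_freq_GhImpCHN[sel_rows] <- sel$freq_GhImpCHN
    truth$trajectory[sel_rows] <- mapply(traj, sel$freq_landrace,
                                         sel$freq_GhImpUSO,
                                         sel$freq_GhImpCHN)
  }
  for (g in c("landrace", "GhImpUSO", "GhImpCHN"))
    truth[[paste0("realized_freq_", g)]] <-
      rowMeans(pres[, groups == g, drop = FALSE])
  depth <- data.frame(accession = acc,
                      mean_depth = ifelse(acc %in% low,
                                          runif(n_acc, 1, 4.9),
                                          runif(n_acc, 8, 30)))
  cov <- NULL
  if (coverage) {
    total <- setNames(models$genes$exonic_length, models$genes$gene_id)
    long_pres <- as.vector(pres)  # gene-major
    frac <- numeric(length(long_pres))
    bp <- config$beta_present; ba <- config$beta_absent
    frac[long_pres == 1L] <- rbeta(sum(long_pres == 1L), bp[1], bp[2])
    frac[long_pres == 0L] <- rbeta(sum(long_pres == 0L), ba[1], ba[2])
    cov <- data.frame(
      accession = rep(acc, each = n_genes),
      gene_id = rep(gene_ids, times = n_acc),
      exonic_bases_total = rep(unname(total[gene_ids]), times = n_acc))
    cov$exonic_bases_covered <- round(frac * cov$exonic_bases_total)
  }
  list(gene_models = models, coverage = cov, depth = depth,
       truth_presence = pres, truth_genes = truth, groups = groups)
}

#' Simulate a phenotype coupled to one PAV
#'
#' `phenotype = effect * presence + Normal(0, noise_sd)`.
#'
#' @param presence binary presence vector for the designated gene.
#' @param effect additive effect of presence.
#' @param noise_sd residual standard deviation (> 0).
#' @param seed RNG seed.
#' @return numeric phenotype vector (names preserved).
#' @export
simulate_phenotype <- function(presence, effect, noise_sd, seed = 1) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!all(presence %in% c(0, 1))) stop("presence must be binary")
  set.seed(seed)
  effect * presence + rnorm(length(presence), 0, noise_sd)
}

#' Write a simulated data set to disk in its external formats
#'
#' Emits VCF (genotypes), GFF3 (gene models), and TSVs (group labels,
#' exon coverage, depths, gene truth table) plus a BED of planted sweep
#' regions, all re-readable by the package's readers.
#'
#' @param geno_sim result of [simulate_genotypes()].
#' @param gene_sim result of [simulate_gene_content()] (with coverage).
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_simulation <- function(geno_sim, gene_sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    groups = file.path(dir, "groups.tsv"),
    gff3 = file.path(dir, "genes.gff3"),
    coverage = file.path(dir, "coverage.tsv"),
    depth = file.path(dir, "depth.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    sweeps = file.path(dir, "truth_sweeps.bed"))
  write_vcf_genotypes(geno_sim$genotypes, paths[["vcf"]])
  write.table(data.frame(accession = names(geno_sim$groups),
                         group = unname(geno_sim$groups)),
              paths[["groups"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gff3_genes(gene_sim$gene_models, paths[["gff3"]])
  if (is.null(gene_sim$coverage))
    stop("gene_sim lacks a coverage table (simulate with coverage = TRUE)")
  write.table(gene_sim$coverage, paths[["coverage"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gene_sim$depth, paths[["depth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gene_sim$truth_genes, paths[["truth_genes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_regions_bed(geno_sim$truth$sweep_regions, paths[["sweeps"]])
  invisible(paths)
}
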