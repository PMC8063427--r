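## Stage-wise PAV selection testing (Fisher + BH-FDR + fold change),
## four-way gain/loss trajectory classification, Bonferroni thresholds,
## PAV-SNP association and QTL overlap, and the presence/absence phenotype
## rank-sum test.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table (a relative tolerance of 1e-7 absorbs floating-point ties) -- the
#' standard two-sided convention.
#'
#' @param a,b,c,d cell counts of the table `[[a, b], [c, d]]` (rows =
#'   groups, columns = present/absent).
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(8, 2, 1, 9)  # 1012/184756
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero table")
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return q-values; monotone in p and never below p.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-group presence/absence frequency table
#'
#' @param pav a [pav_matrix()] or plain 0/1 matrix (genes x accessions).
#' @param groups named character vector accession -> group; only accessions
#'   present in both are used.
#' @param group_levels the three stage groups, earliest first (default
#'   `c("landrace", "GhImpUSO", "GhImpCHN")`).
#' @param exclude accession IDs to drop (e.g. mixed-ancestry accessions
#'   excluded from frequency comparisons).
#' @param high_depth_only restrict to high-depth accessions when `pav` is a
#'   `pav_matrix` (default TRUE).
#' @param drop_singletons drop singleton genes first (default TRUE; see
#'   [detect_singletons()]).
#' @return data.frame of class `frequency_table` with one row per gene:
#'   `gene_id` and, per group `x`, `present_x`, `absent_x`, `freq_x`.
#'   Attribute `group_sizes` records accessions per group.
#' @export
presence_frequency <- function(pav, groups,
                               group_levels = c("landrace", "GhImpUSO",
                                                "GhImpCHN"),
                               exclude = NULL, high_depth_only = TRUE,
                               drop_singletons = TRUE) {
  if (inherits(pav, "pav_matrix")) {
    m <- pav$presence
    if (drop_singletons) {
      sg <- detect_singletons(pav)
      m <- m[setdiff(rownames(m), sg), , drop = FALSE]
    }
    if (high_depth_only)
      m <- m[, names(pav$depth_class)[pav$depth_class == "high"],
             drop = FALSE]
  } else m <- pav
  keep <- setdiff(intersect(colnames(m), names(groups)), exclude)
  m <- m[, keep, drop = FALSE]
  gl <- groups[keep]
  out <- data.frame(gene_id = rownames(m))
  sizes <- integer(0)
  for (g in group_levels) {
    acc <- names(gl)[gl == g]
    if (!length(acc)) stop("empty group: ", g)
    sizes[g] <- length(acc)
    pres <- rowSums(m[, acc, drop = FALSE])
    out[[paste0("present_", g)]] <- as.integer(pres)
    out[[paste0("absent_", g)]] <- as.integer(length(acc) - pres)
    out[[paste0("freq_", g)]] <- pres / length(acc)
  }
  structure(out, group_sizes = sizes,
            group_levels = group_levels,
            class = c("frequency_table", "data.frame"))
}

.stage_groups <- function(stage, group_levels) {
  switch(stage,
         domestication = group_levels[1:2],
         improvement = group_levels[2:3],
         stop("unknown stage: ", stage))
}

#' Stage-wise favorable/unfavorable selection calls
#'
#' For each gene, a two-sided Fisher's exact test compares presence/absence
#' counts between the earlier and later group of a stage
#' (domestication: landrace vs GhImpUSO; improvement: GhImpUSO vs
#' GhImpCHN); p-values are BH-FDR corrected across all tested genes of the
#' stage. Fold change is the frequency ratio earlier/later (`Inf` when the
#' later frequency is 0 and the earlier is positive, which qualifies as
#' `> fc_bounds[2]`). Verdicts: `favorable` when `q < fdr_max` and
#' `FC < fc_bounds[1]` (frequency rose); `unfavorable` when `q < fdr_max`
#' and `FC > fc_bounds[2]` (frequency fell); otherwise `none`. Genes with
#' both frequencies 0 are untested.
#'
#' @param freq a [presence_frequency()] table.
#' @param stage `"domestication"` or `"improvement"`.
#' @param fdr_max FDR threshold (default 0.001).
#' @param fc_bounds lower/upper fold-change bounds (default `c(0.5, 2)`).
#' @return data.frame: `gene_id`, `stage`, `tested`, `fisher_p`, `fdr_q`,
#'   `fold_change`, `verdict`.
#' @export
classify_stage_selection <- function(freq, stage = c("domestication",
                                                     "improvement"),
                                     fdr_max = 0.001,
                                     fc_bounds = c(0.5, 2)) {
  stage <- match.arg(stage)
  gl <- attr(freq, "group_levels")
  gs <- .stage_groups(stage, gl)
  pe <- freq[[paste0("present_", gs[1])]]
  ae <- freq[[paste0("absent_", gs[1])]]
  pl <- freq[[paste0("present_", gs[2])]]
  al <- freq[[paste0("absent_", gs[2])]]
  fe <- freq[[paste0("freq_", gs[1])]]
  fl <- freq[[paste0("freq_", gs[2])]]
  tested <- !(fe == 0 & fl == 0)
  p <- rep(NA_real_, nrow(freq))
  p[tested] <- mapply(fisher_exact_2x2, pe[tested], ae[tested], pl[tested],
                      al[tested])
  q <- rep(NA_real_, nrow(freq))
  q[tested] <- bh_fdr(p[tested])
  fc <- ifelse(fl > 0, fe / fl, ifelse(fe > 0, Inf, NA_real_))
  verdict <- rep("none", nrow(freq))
  sig <- tested & !is.na(q) & q < fdr_max
  verdict[sig & fc < fc_bounds[1]] <- "favorable"
  verdict[sig & fc > fc_bounds[2]] <- "unfavorable"
  data.frame(gene_id = freq$gene_id, stage = stage, tested = tested,
             fisher_p = p, fdr_q = q, fold_change = fc, verdict = verdict)
}

#' Four-way presence-frequency trajectory
#'
#' Classifies each gene's frequency path across (landrace, GhImpUSO,
#' GhImpCHN) with strict inequalities: `favorable_gain`
#' (CHN > USO > landrace), `favorable_loss` (USO > landrace and
#' CHN < USO), `unfavorable_gain` (landrace > USO and CHN > USO),
#' `unfavorable_loss` (CHN < USO < landrace). Ties match no chain and give
#' `none`. The chains are mutually exclusive by construction.
#'
#' @param freq a [presence_frequency()] table (or data.frame with the three
#'   `freq_*` columns).
#' @param group_levels stage order, earliest first.
#' @return character vector of trajectories, named by gene.
#' @export
classify_trajectory <- function(freq,
                                group_levels = attr(freq, "group_levels")) {
  if (is.null(group_levels))
    group_levels <- c("landrace", "GhImpUSO", "GhImpCHN")
  fL <- freq[[paste0("freq_", group_levels[1])]]
  fU <- freq[[paste0("freq_", group_levels[2])]]
  fC <- freq[[paste0("freq_", group_levels[3])]]
  out <- rep("none", length(fL))
  out[fC > fU & fU > fL] <- "favorable_gain"
  out[fU > fL & fC < fU] <- "favorable_loss"
  out[fL > fU & fC > fU] <- "unfavorable_gain"
  out[fC < fU & fU < fL] <- "unfavorable_loss"
  setNames(out, freq$gene_id)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1].
#' @param n_tests number of tests (e.g. SNPs).
#' @return list with `threshold` (`alpha / n_tests`) and `neg_log10`.
#' @examples
#' bonferroni_threshold(0.05, 2291437)  # 2.18e-8
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (n_tests < 1) stop("n_tests must be >= 1")
  thr <- alpha / n_tests
  list(threshold = thr, neg_log10 = -log10(thr))
}

#' Unstructured PAV-SNP association
#'
#' Treats a gene's presence/absence as the phenotype and tests each SNP
#' with a 2x2 allelic Fisher's exact test (allele count x presence class).
#' No population-structure correction is applied -- this is an unstructured
#' association intended for threshold bookkeeping and QTL overlap, not a
#' mixed-model GWAS. SNPs with `p < alpha / N` (N = SNPs tested) are
#' flagged.
#'
#' @param presence named binary vector (accession -> 0/1) for one PAV gene.
#' @param gt a [genotype_matrix()] on (a superset of) the same accessions.
#' @param alpha family-wise alpha for the Bonferroni threshold
#'   (default 0.05).
#' @return list of class `pav_association`: `p` (per-SNP p-values),
#'   `threshold`, `n_tests`, `significant` (data.frame `chrom`, `pos` of
#'   flagged SNPs, position-sorted).
#' @export
pav_snp_association <- function(presence, gt, alpha = 0.05) {
  stopifnot(inherits(gt, "genotype_matrix"))
  acc <- intersect(names(presence), gt$samples)
  if (length(acc) < 2L) stop("fewer than two shared accessions")
  pv <- presence[acc]
  if (length(unique(pv)) < 2L)
    stop("PAV vector is constant; association is untestable")
  g <- gt$geno[, acc, drop = FALSE]
  idx1 <- pv == 1
  alt1 <- rowSums(g[, idx1, drop = FALSE], na.rm = TRUE)
  n1 <- 2 * rowSums(!is.na(g[, idx1, drop = FALSE]))
  alt0 <- rowSums(g[, !idx1, drop = FALSE], na.rm = TRUE)
  n0 <- 2 * rowSums(!is.na(g[, !idx1, drop = FALSE]))
  n_tests <- nrow(g)
  p <- vapply(seq_len(n_tests), function(i) {
    if (n1[i] == 0 || n0[i] == 0) return(NA_real_)
    fisher_exact_2x2(alt1[i], n1[i] - alt1[i], alt0[i], n0[i] - alt0[i])
  }, numeric(1))
  thr <- bonferroni_threshold(alpha, n_tests)$threshold
  sig <- which(!is.na(p) & p < thr)
  sig <- sig[order(gt$chrom[sig], gt$pos[sig])]
  structure(list(p = p, threshold = thr, n_tests = n_tests,
                 significant = data.frame(chrom = gt$chrom[sig],
                                          pos = gt$pos[sig])),
            class = "pav_association")
}

#' Overlap significant positions with QTL intervals
#'
#' Membership is half-open: position `pos` lies in a QTL iff
#' `start <= pos < end`.
#'
#' @param positions data.frame with `chrom`, `pos` (0-based), e.g. the
#'   `significant` element of [pav_snp_association()].
#' @param qtls QTL table (see [read_qtl_table()]).
#' @return data.frame of overlapped QTL rows, one per (position, QTL) hit,
#'   with `chrom`, `pos`, `qtl_id`, `trait`, `origin`.
#' @export
overlap_with_qtl <- function(positions, qtls) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      qtl_id = character(), trait = character(),
                      origin = character())
  if (nrow(positions) == 0L || nrow(qtls) == 0L) return(empty)
  pgr <- GenomicRanges::GRanges(positions$chrom,
                                IRanges::IRanges(positions$pos + 1,
                                                 width = 1))
  qgr <- GenomicRanges::GRanges(qtls$chrom,
                                IRanges::IRanges(qtls$start + 1, qtls$end))
  hits <- GenomicRanges::findOverlaps(pgr, qgr)
  if (!length(hits)) return(empty)
  pi <- S4Vectors::queryHits(hits); qi <- S4Vectors::subjectHits(hits)
  data.frame(chrom = positions$chrom[pi], pos = positions$pos[pi],
             qtl_id = qtls$qtl_id[qi], trait = qtls$trait[qi],
             origin = qtls$origin[qi])
}

#' Wilcoxon rank-sum test for a presence/absence phenotype contrast
#'
#' Two-sided; exact enumeration when the combined sample size is at most 10
#' and there are no ties, otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param phenotypes numeric phenotype vector.
#' @param presence binary vector (same length) splitting accessions into
#'   presence/absence classes; each class needs at least 2 observations.
#' @return two-sided p-value.
#' @export
rank_sum_presence_test <- function(phenotypes, presence) {
  stopifnot(length(phenotypes) == length(presence))
  x <- phenotypes[presence == 1]
  y <- phenotypes[presence == 0]
  if (length(x) < 2L || length(y) < 2L)
    stop("each presence class needs at least 2 observations")
  if (length(unique(c(x, y))) == 1L) return(1)  # degenerate: no information
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (n <= 10L && !ties)
    wilcox.test(x, y, exact = TRUE)$p.value
  else
    suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}
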