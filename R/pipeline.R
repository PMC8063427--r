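## End-to-end orchestration: simulate -> filter -> scan -> call-pav ->
## classify -> saturate -> select -> associate, with a JSON run manifest.

#' Pipeline configuration
#'
#' Stage toggles plus every stage parameter, all defaulting to the
#' conventions the individual functions document (100 kb / 20 kb windows,
#' ratio thresholds 15 and 2, presence cutoff 0.8, softcore/cloud
#' thresholds 0.97/0.01, FDR 0.001, fold-change bounds 0.5/2, alpha 0.05).
#'
#' @param sim a [sim_config()]; drives the `simulate` stage and seeds the
#'   run.
#' @param stages character vector of stages to run, in dependency order.
#' @param inputs named list of file paths (`vcf`, `groups`, `coverage`,
#'   `depth`, `gff3`) used when `simulate` is not among the stages.
#' @param window_size,step sliding-window grid in bp.
#' @param ratio_min,improvement_ratio_min diversity-ratio thresholds for
#'   the domestication (landrace vs pooled improved) and improvement
#'   (GhImpUSO vs GhImpCHN) scans.
#' @param score_track optional path to an external score track (e.g.
#'   XP-CLR); when given, domestication regions are intersected with its
#'   top-`top_q` windows.
#' @param top_q upper quantile of the score track.
#' @param maf_min,missing_max,min_hom variant-filter cascade parameters.
#' @param call a [call_params()] object.
#' @param thresholds a [class_thresholds()] object.
#' @param fdr_max,fc_bounds selection-test parameters.
#' @param alpha family-wise alpha for PAV-SNP association.
#' @param pav_maf_min minimum PAV minor presence frequency for association.
#' @param n_orderings,n_replicates saturation sampling.
#' @param qtl optional path to a QTL table.
#' @param exclude accessions excluded from frequency comparisons.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "filter", "scan",
                                       "call_pav", "classify", "saturate",
                                       "select", "associate"),
                            inputs = list(),
                            window_size = 1e5, step = 2e4,
                            ratio_min = 15, improvement_ratio_min = 2,
                            score_track = NULL, top_q = 0.05,
                            maf_min = 0.01, missing_max = 0.8, min_hom = 5,
                            call = call_params(),
                            thresholds = class_thresholds(),
                            fdr_max = 0.001, fc_bounds = c(0.5, 2),
                            alpha = 0.05, pav_maf_min = 0.02,
                            n_orderings = 200, n_replicates = 5,
                            qtl = NULL, exclude = NULL) {
  cfg <- as.list(environment())
  known <- c("simulate", "filter", "scan", "call_pav", "classify",
             "saturate", "select", "associate")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the PAV analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes every stage
#' output plus a JSON manifest (parameters, seed, output digests, warning
#' counts) under `out_dir`. Identical config and seed produce byte-identical
#' outputs. A stage whose inputs are unavailable (e.g. `filter` without
#' `simulate` or an `inputs$vcf`) fails with an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  outputs <- character(0)
  counts <- list()
  warnings <- list(gray_zone_calls = 0L, infinite_ratios = 0L,
                   infinite_fold_changes = 0L)
  need <- function(x, stage, what)
    if (is.null(x)) stop("stage '", stage, "' requires ", what,
                         " (enable the producing stage or supply inputs)")
  gt <- NULL; groups <- NULL; layout <- NULL
  coverage <- NULL; depth <- NULL; models <- NULL
  pav <- NULL; freq <- NULL

  if ("simulate" %in% stages) {
    gs <- simulate_genotypes(config$sim)
    cs <- simulate_gene_content(config$sim)
    paths <- write_simulation(gs, cs, file.path(out_dir, "sim"))
    outputs <- c(outputs, unname(paths))
    gt <- gs$genotypes; groups <- gs$groups; layout <- gs$layout
    coverage <- cs$coverage; depth <- cs$depth; models <- cs$gene_models
    counts$simulate <- list(n_sites = nrow(gt$geno),
                            n_accessions = ncol(gt$geno),
                            n_genes = nrow(models$genes))
  } else {
    inp <- config$inputs
    if (!is.null(inp$vcf)) gt <- read_vcf_genotypes(inp$vcf)
    if (!is.null(inp$groups)) groups <- read_group_labels(inp$groups)
    if (!is.null(inp$coverage)) coverage <- read_coverage_table(inp$coverage)
    if (!is.null(inp$depth))
      depth <- read.delim(inp$depth, stringsAsFactors = FALSE)
    if (!is.null(inp$gff3)) models <- read_gff3_genes(inp$gff3)
    if (!is.null(gt))
      layout <- genome_layout(tapply(gt$pos + 1L, gt$chrom, max) * 1.05)
  }

  if ("filter" %in% stages) {
    need(gt, "filter", "genotypes")
    n0 <- nrow(gt$geno)
    gt <- filter_indels(core_variant_filter(
      filter_biallelic(gt, config$maf_min, config$missing_max),
      config$min_hom))
    p <- file.path(out_dir, "core_variants.vcf")
    write_vcf_genotypes(gt, p)
    outputs <- c(outputs, p)
    counts$filter <- list(input_sites = n0, retained_sites = nrow(gt$geno))
  }

  if ("scan" %in% stages) {
    need(gt, "scan", "genotypes"); need(groups, "scan", "group labels")
    windows <- make_windows(layout, config$window_size, config$step)
    track <- window_diversity(gt, groups, windows,
                              pops = list(landrace = "landrace",
                                          improved = c("GhImpUSO",
                                                       "GhImpCHN"),
                                          GhImpUSO = "GhImpUSO",
                                          GhImpCHN = "GhImpCHN"))
    fst <- weir_cockerham_fst(gt, .pop_samples(groups, "landrace"),
                              .pop_samples(groups, c("GhImpUSO",
                                                     "GhImpCHN")), windows)
    track$fst <- fst$fst
    dom <- ratio_regions(track, "landrace", "improved", config$ratio_min,
                         label = "domestication")
    imp <- ratio_regions(track, "GhImpUSO", "GhImpCHN",
                         config$improvement_ratio_min,
                         label = "improvement")
    warnings$infinite_ratios <- attr(dom, "n_infinite") +
      attr(imp, "n_infinite")
    if (!is.null(config$score_track)) {
      st <- read_score_track(config$score_track, layout)
      top <- top_quantile_regions(st, q = config$top_q,
                                  gap_max = config$step)
      dom <- merge_regions(intersect_regions(dom, top,
                                             label = "domestication"),
                           gap_max = config$step)
    }
    p1 <- file.path(out_dir, "diversity_track.tsv")
    p2 <- file.path(out_dir, "domestication_regions.bed")
    p3 <- file.path(out_dir, "improvement_regions.bed")
    .write_tsv(as.data.frame(track), p1)
    write_regions_bed(dom, p2); write_regions_bed(imp, p3)
    outputs <- c(outputs, p1, p2, p3)
    if (!is.null(models)) {
      ag <- assign_genes_to_regions(dom, models)
      p4 <- .write_tsv(ag, file.path(out_dir, "domestication_genes.tsv"))
      outputs <- c(outputs, p4)
      counts$scan_genes <- list(n_domestication_genes =
                                  length(unique(ag$gene_id)))
    }
    counts$scan <- list(n_windows = nrow(track),
                        n_domestication_regions = nrow(dom),
                        n_improvement_regions = nrow(imp))
  }

  if ("call_pav" %in% stages) {
    need(coverage, "call_pav", "an exon-coverage table")
    need(depth, "call_pav", "a depth table")
    src <- if (!is.null(models))
      setNames(models$genes$source, models$genes$gene_id) else NULL
    pav <- build_pav_matrix(coverage, depth, config$call, gene_source = src)
    warnings$gray_zone_calls <- pav$n_gray_zone
    p <- file.path(out_dir, "pav_matrix.tsv")
    write_pav_matrix(pav$presence, p)
    outputs <- c(outputs, p)
    counts$call_pav <- list(n_genes = nrow(pav$presence),
                            n_low_depth = sum(pav$depth_class == "low"))
  }

  if ("classify" %in% stages) {
    need(pav, "classify", "a PAV matrix")
    singletons <- detect_singletons(pav)
    keep <- setdiff(rownames(pav$presence), singletons)
    sub <- pav
    sub$presence <- pav$presence[keep, , drop = FALSE]
    sub$gene_source <- pav$gene_source[keep]
    cls <- classify_pan_genes(sub, thresholds = config$thresholds)
    summ <- category_summary(cls, total_pan_genes = nrow(pav$presence),
                             n_singleton = length(singletons))
    p1 <- .write_tsv(cls$classes, file.path(out_dir, "classification.tsv"))
    p2 <- file.path(out_dir, "classification.json")
    jsonlite::write_json(list(
      n_accessions = cls$n_accessions,
      softcore_min_count = cls$softcore_min_count,
      cloud_max_count = cls$cloud_max_count,
      categories = summ$table,
      variable_count = summ$variable_count,
      variable_pct = summ$variable_pct,
      singletons = singletons), p2, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p1, p2)
    counts$classify <- as.list(cls$counts)
    counts$classify$singleton <- length(singletons)
  }

  if ("saturate" %in% stages) {
    need(pav, "saturate", "a PAV matrix")
    sat <- saturation_curve(pav, config$n_orderings, config$n_replicates,
                            seed = config$sim$seed)
    p <- .write_tsv(as.data.frame(sat), file.path(out_dir,
                                                  "saturation.tsv"))
    outputs <- c(outputs, p)
    counts$saturate <- list(pan_at_N = sat$pan_mean[nrow(sat)],
                            core_at_N = sat$core_mean[nrow(sat)])
  }

  if ("select" %in% stages) {
    need(pav, "select", "a PAV matrix")
    need(groups, "select", "group labels")
    freq <- presence_frequency(pav, groups, exclude = config$exclude)
    dom <- classify_stage_selection(freq, "domestication", config$fdr_max,
                                    config$fc_bounds)
    imp <- classify_stage_selection(freq, "improvement", config$fdr_max,
                                    config$fc_bounds)
    sel <- rbind(dom, imp)
    sel$trajectory <- rep(unname(classify_trajectory(freq)), 2L)
    warnings$infinite_fold_changes <-
      sum(is.infinite(sel$fold_change), na.rm = TRUE)
    p <- .write_tsv(sel, file.path(out_dir, "selection.tsv"))
    outputs <- c(outputs, p)
    counts$select <- list(
      favorable_domestication = sum(dom$verdict == "favorable"),
      unfavorable_domestication = sum(dom$verdict == "unfavorable"),
      favorable_improvement = sum(imp$verdict == "favorable"),
      unfavorable_improvement = sum(imp$verdict == "unfavorable"))
  }

  if ("associate" %in% stages) {
    need(pav, "associate", "a PAV matrix")
    need(gt, "associate", "genotypes")
    high <- names(pav$depth_class)[pav$depth_class == "high"]
    m <- pav$presence[, high, drop = FALSE]
    f <- rowMeans(m)
    maf <- pmin(f, 1 - f)
    cand <- rownames(m)[maf >= config$pav_maf_min]
    qtls <- if (!is.null(config$qtl)) read_qtl_table(config$qtl) else NULL
    rows <- lapply(cand, function(g) {
      as_res <- pav_snp_association(m[g, ], gt, config$alpha)
      hits <- if (!is.null(qtls))
        overlap_with_qtl(as_res$significant, qtls) else NULL
      data.frame(gene_id = g, n_sig_snps = nrow(as_res$significant),
                 threshold = as_res$threshold,
                 qtl_ids = if (is.null(hits) || nrow(hits) == 0L) ""
                           else paste(unique(hits$qtl_id), collapse = ","))
    })
    assoc <- if (length(rows)) do.call(rbind, rows)
             else data.frame(gene_id = character(), n_sig_snps = integer(),
                             threshold = numeric(), qtl_ids = character())
    p <- .write_tsv(assoc, file.path(out_dir, "association.tsv"))
    outputs <- c(outputs, p)
    counts$associate <- list(n_pavs_tested = length(cand),
                             n_pavs_with_hits = sum(assoc$n_sig_snps > 0))
  }

  manifest <- list(
    package = "panpav",
    version = as.character(utils::packageVersion("panpav")),
    seed = config$sim$seed,
    stages = stages,
    parameters = list(
      window_size = config$window_size, step = config$step,
      ratio_min = config$ratio_min,
      improvement_ratio_min = config$improvement_ratio_min,
      top_q = config$top_q, maf_min = config$maf_min,
      missing_max = config$missing_max, min_hom = config$min_hom,
      presence_fraction = config$call$presence_fraction,
      lost_cutoff = config$call$lost_cutoff,
      low_depth_threshold = config$call$low_depth_threshold,
      softcore_min_fraction = config$thresholds$softcore_min_fraction,
      cloud_max_fraction = config$thresholds$cloud_max_fraction,
      fdr_max = config$fdr_max, fc_bounds = config$fc_bounds,
      alpha = config$alpha, pav_maf_min = config$pav_maf_min,
      n_orderings = config$n_orderings,
      n_replicates = config$n_replicates),
    counts = counts,
    warnings = warnings,
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
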