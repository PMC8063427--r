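## Gene presence calling from exon coverage, PAV matrix assembly,
## core/softcore/shell/cloud classification and saturation-curve modeling.

#' Presence-calling parameters
#'
#' `min_cov` is the read depth at which an exonic base counts as covered
#' (applied upstream when the coverage table is produced); a gene is called
#' present when strictly more than `presence_fraction` of its exonic bases
#' are covered. `lost_cutoff` bounds the gray zone reported alongside calls:
#' fractions in `(lost_cutoff, presence_fraction]` are ambiguous
#' (neither confidently present nor confidently lost) and are treated as
#' absent by default.
#'
#' @param min_cov minimum covering read depth (default 2).
#' @param presence_fraction exonic coverage fraction above which a gene is
#'   present (default 0.8, strict inequality).
#' @param lost_cutoff coverage fraction below which a gene is confidently
#'   lost (default 0.2).
#' @param low_depth_threshold genome-wide mean depth below which an
#'   accession is flagged low-depth (default 5).
#' @return list of class `call_params`.
#' @export
call_params <- function(min_cov = 2, presence_fraction = 0.8,
                        lost_cutoff = 0.2, low_depth_threshold = 5) {
  if (!(lost_cutoff >= 0 && lost_cutoff <= presence_fraction &&
        presence_fraction <= 1))
    stop("need 0 <= lost_cutoff <= presence_fraction <= 1")
  structure(list(min_cov = min_cov, presence_fraction = presence_fraction,
                 lost_cutoff = lost_cutoff,
                 low_depth_threshold = low_depth_threshold),
            class = "call_params")
}

#' Call gene presence from exonic coverage fractions
#'
#' @param covered,total exonic bases covered (at depth >= `min_cov`) and
#'   total exonic bases; vectors are recycled against each other.
#' @param params a [call_params()] object.
#' @return list with logical vectors `present` (fraction strictly above the
#'   presence cutoff) and `gray_zone` (fraction in
#'   `(lost_cutoff, presence_fraction]`).
#' @examples
#' call_gene_presence(c(85, 80, 50), 100)
#' @export
call_gene_presence <- function(covered, total, params = call_params()) {
  if (any(total <= 0)) stop("total exonic bases must be positive")
  if (any(covered < 0) || any(covered > total))
    stop("covered bases must lie in [0, total]")
  frac <- covered / total
  present <- frac > params$presence_fraction
  gray <- !present & frac > params$lost_cutoff
  list(present = present, gray_zone = gray)
}

#' Construct a PAV matrix object
#'
#' @param presence integer 0/1 matrix, genes x accessions, with dimnames.
#' @param depth_class named character vector ("high"/"low") per accession;
#'   default all "high".
#' @param gene_source named character vector
#'   ("reference"/"non_reference") per gene; default all "reference".
#' @param n_gray_zone count of gray-zone calls folded into absences
#'   (bookkeeping).
#' @return object of class `pav_matrix`.
#' @export
pav_matrix <- function(presence, depth_class = NULL, gene_source = NULL,
                       n_gray_zone = 0L) {
  stopifnot(is.matrix(presence), !is.null(rownames(presence)),
            !is.null(colnames(presence)))
  if (anyNA(presence) || !all(presence %in% c(0L, 1L)))
    stop("presence values must be 0 or 1")
  storage.mode(presence) <- "integer"
  acc <- colnames(presence)
  if (is.null(depth_class)) depth_class <- setNames(rep("high", length(acc)), acc)
  if (!all(acc %in% names(depth_class)))
    stop("depth_class must cover every accession")
  if (!all(depth_class[acc] %in% c("high", "low")))
    stop("depth_class values must be 'high' or 'low'")
  if (is.null(gene_source))
    gene_source <- setNames(rep("reference", nrow(presence)),
                            rownames(presence))
  structure(list(presence = presence,
                 depth_class = depth_class[acc],
                 gene_source = gene_source[rownames(presence)],
                 n_gray_zone = n_gray_zone),
            class = "pav_matrix")
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat("<pav_matrix> ", nrow(x$presence), " genes x ", ncol(x$presence),
      " accessions (", sum(x$depth_class == "low"), " low-depth; ",
      x$n_gray_zone, " gray-zone calls)\n", sep = "")
  invisible(x)
}

#' Build a PAV matrix from an exon-coverage table
#'
#' @param coverage data.frame with columns `accession`, `gene_id`,
#'   `exonic_bases_covered`, `exonic_bases_total`; every
#'   (accession, gene) pair must be present exactly once.
#' @param depth data.frame with columns `accession`, `mean_depth`
#'   (genome-wide mean sequencing depth).
#' @param params a [call_params()] object.
#' @param gene_source optional named vector of gene provenance.
#' @return A [pav_matrix()] with accessions depth-classified at
#'   `low_depth_threshold`.
#' @export
build_pav_matrix <- function(coverage, depth, params = call_params(),
                             gene_source = NULL) {
  need <- c("accession", "gene_id", "exonic_bases_covered",
            "exonic_bases_total")
  stopifnot(all(need %in% names(coverage)),
            all(c("accession", "mean_depth") %in% names(depth)))
  genes <- sort(unique(coverage$gene_id))
  accs <- sort(unique(coverage$accession))
  ij <- cbind(match(coverage$gene_id, genes),
              match(coverage$accession, accs))
  filled <- matrix(FALSE, length(genes), length(accs))
  filled[ij] <- TRUE
  if (!all(filled)) {
    miss <- which(!filled, arr.ind = TRUE)[1L, ]
    stop("missing coverage row for accession '", accs[miss[2L]],
         "', gene '", genes[miss[1L]], "'")
  }
  if (any(duplicated(ij)))
    stop("duplicated (accession, gene) coverage rows")
  call <- call_gene_presence(coverage$exonic_bases_covered,
                             coverage$exonic_bases_total, params)
  pres <- matrix(0L, length(genes), length(accs),
                 dimnames = list(genes, accs))
  pres[ij] <- as.integer(call$present)
  md <- setNames(depth$mean_depth, depth$accession)
  if (!all(accs %in% names(md)))
    stop("depth table missing accession(s): ",
         paste(head(setdiff(accs, names(md)), 5), collapse = ", "))
  dc <- ifelse(md[accs] < params$low_depth_threshold, "low", "high")
  pav_matrix(pres, depth_class = setNames(dc, accs),
             gene_source = gene_source, n_gray_zone = sum(call$gray_zone))
}

#' Detect singleton genes
#'
#' Genes present only in low-depth accessions (sequencing depth below the
#' calling threshold) are flagged singleton; they are excluded from
#' frequency-based classification and selection analysis because their
#' apparent restriction may reflect missed detection rather than biology.
#'
#' @param pav a [pav_matrix()].
#' @return character vector of singleton gene IDs.
#' @export
detect_singletons <- function(pav) {
  stopifnot(inherits(pav, "pav_matrix"))
  low <- pav$depth_class == "low"
  m <- pav$presence
  n_low <- rowSums(m[, low, drop = FALSE])
  n_high <- rowSums(m[, !low, drop = FALSE])
  rownames(m)[n_low > 0L & n_high == 0L]
}

#' Pan-gene class thresholds
#'
#' @param softcore_min_fraction minimum presence fraction for softcore
#'   (default 0.97).
#' @param cloud_max_fraction maximum presence fraction for cloud (default
#'   0.01; 0.02 is the convention for smaller panels such as the
#'   *G. barbadense* set).
#' @return list of class `class_thresholds`.
#' @export
class_thresholds <- function(softcore_min_fraction = 0.97,
                             cloud_max_fraction = 0.01) {
  if (!(cloud_max_fraction < softcore_min_fraction))
    stop("cloud_max_fraction must be below softcore_min_fraction")
  structure(list(softcore_min_fraction = softcore_min_fraction,
                 cloud_max_fraction = cloud_max_fraction),
            class = "class_thresholds")
}

#' Classify pan genes as core / softcore / shell / cloud
#'
#' With presence count `c` among the `N` high-depth accessions:
#' core iff `c == N`; softcore iff `ceiling(f_soft * N) <= c <= N - 1`;
#' cloud iff `1 <= c <= floor(f_cloud * N)`; shell otherwise. The ceiling /
#' floor pairing is the one that reproduces the canonical boundary ranges
#' (990-1019 softcore and 11-989 shell at N = 1020 with f = 0.97/0.01;
#' 172-176 and 4-171 at N = 177 with f = 0.97/0.02). Genes with `c == 0`
#' are reported separately as absent-in-panel. Singletons must be removed
#' beforehand (see [detect_singletons()]).
#'
#' @param x a [pav_matrix()] (counts taken over high-depth accessions), or
#'   a named integer vector of presence counts.
#' @param n_accessions panel size `N`; required when `x` is a count vector,
#'   otherwise taken as the number of high-depth accessions.
#' @param thresholds a [class_thresholds()] object.
#' @return object of class `pan_classification`: list with `classes`
#'   (data.frame `gene_id`, `presence_count`, `class`), `n_accessions`,
#'   `softcore_min_count`, `cloud_max_count`, and `counts` per category.
#' @export
classify_pan_genes <- function(x, n_accessions = NULL,
                               thresholds = class_thresholds()) {
  if (inherits(x, "pav_matrix")) {
    high <- names(x$depth_class)[x$depth_class == "high"]
    counts <- rowSums(x$presence[, high, drop = FALSE])
    n <- length(high)
  } else {
    counts <- x
    if (is.null(names(counts)))
      names(counts) <- paste0("gene", seq_along(counts))
    n <- n_accessions
  }
  if (is.null(n) || n < 1) stop("panel size N must be a positive integer")
  if (any(counts < 0) || any(counts > n))
    stop("presence counts must lie in [0, N]")
  soft_min <- as.integer(ceiling(thresholds$softcore_min_fraction * n))
  cloud_max <- as.integer(floor(thresholds$cloud_max_fraction * n))
  cls <- ifelse(counts == n, "core",
         ifelse(counts >= soft_min, "softcore",
         ifelse(counts == 0, "absent",
         ifelse(counts <= cloud_max, "cloud", "shell"))))
  lev <- c("core", "softcore", "shell", "cloud", "absent")
  structure(list(
    classes = data.frame(gene_id = names(counts),
                         presence_count = as.integer(counts),
                         class = cls),
    n_accessions = as.integer(n),
    softcore_min_count = soft_min,
    cloud_max_count = cloud_max,
    counts = table(factor(cls, levels = lev))
  ), class = "pan_classification")
}

#' @export
print.pan_classification <- function(x, ...) {
  cat("<pan_classification> N =", x$n_accessions,
      "| softcore >=", x$softcore_min_count,
      "| cloud <=", x$cloud_max_count, "\n")
  print(x$counts)
  invisible(x)
}

#' Category bookkeeping: counts and percentages of total pan genes
#'
#' @param counts named numeric vector of per-category gene counts
#'   (`core`, `softcore`, `shell`, `cloud`, `singleton`; any subset), or a
#'   `pan_classification` (singletons then passed via `n_singleton`).
#' @param total_pan_genes denominator for percentages (the full pan-gene
#'   catalogue size).
#' @param n_singleton singleton count to add when `counts` is a
#'   classification object.
#' @param digits percentage rounding (default 2).
#' @return list with `table` (category, count, pct), `variable_count`
#'   (softcore + shell + cloud + singleton) and `variable_pct`.
#' @examples
#' category_summary(c(softcore = 5941, shell = 3803, cloud = 12434,
#'                    singleton = 17100), total_pan_genes = 102768)
#' @export
category_summary <- function(counts, total_pan_genes, n_singleton = 0,
                             digits = 2) {
  if (inherits(counts, "pan_classification")) {
    cnt <- as.numeric(counts$counts[c("core", "softcore", "shell", "cloud")])
    counts <- c(setNames(cnt, c("core", "softcore", "shell", "cloud")),
                singleton = n_singleton)
  }
  if (is.null(names(counts))) stop("category counts must be named")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (total_pan_genes < sum(counts))
    stop("total_pan_genes smaller than the category sum")
  tab <- data.frame(category = names(counts),
                    count = as.numeric(counts),
                    pct = round(100 * as.numeric(counts) / total_pan_genes,
                                digits))
  var_cat <- intersect(c("softcore", "shell", "cloud", "singleton"),
                       names(counts))
  vc <- sum(counts[var_cat])
  list(table = tab, variable_count = vc,
       variable_pct = round(100 * vc / total_pan_genes, digits))
}

#' Pan- and core-genome saturation curves
#'
#' For each of `n_orderings * n_replicates` random accession orderings the
#' cumulative union (pan) and intersection (core) gene counts are recorded
#' at every prefix length `k`; the curve reports mean/min/max per `k`
#' across all orderings. Along any single ordering pan is non-decreasing
#' and core non-increasing; at `k = N` both are ordering-invariant.
#'
#' @param pav a [pav_matrix()] (restricted internally to high-depth
#'   accessions) or a plain 0/1 gene x accession matrix.
#' @param n_orderings random orderings per replicate batch (default 200).
#' @param n_replicates replicate batches (default 5; the defaults multiply
#'   to the customary 1000 total orderings).
#' @param seed RNG seed for reproducible sampling.
#' @return data.frame of class `saturation_curve`: `k`, `pan_mean`,
#'   `pan_min`, `pan_max`, `core_mean`, `core_min`, `core_max`, for
#'   `k = 2..N`.
#' @export
saturation_curve <- function(pav, n_orderings = 200, n_replicates = 5,
                             seed = 1) {
  m <- if (inherits(pav, "pav_matrix")) {
    high <- names(pav$depth_class)[pav$depth_class == "high"]
    pav$presence[, high, drop = FALSE]
  } else pav
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 accessions for a saturation curve")
  n_tot <- n_orderings * n_replicates
  set.seed(seed)
  pan <- core <- matrix(0L, n_tot, n)
  any_row <- rowSums(m) > 0L
  all_row <- rowSums(m) == n
  for (i in seq_len(n_tot)) {
    ord <- sample.int(n)
    mo <- m[, ord, drop = FALSE]
    ## first accession (in this ordering) where each gene appears / drops out
    first_pres <- max.col(mo, ties.method = "first")
    first_pres[rowSums(mo) == 0L] <- n + 1L
    first_abs <- max.col(1L - mo, ties.method = "first")
    first_abs[all_row] <- n + 1L
    pan[i, ] <- cumsum(tabulate(first_pres, nbins = n))
    core[i, ] <- nrow(m) - cumsum(tabulate(first_abs, nbins = n))
  }
  ks <- 2:n
  out <- data.frame(
    k = ks,
    pan_mean = colMeans(pan)[ks],
    pan_min = apply(pan, 2L, min)[ks],
    pan_max = apply(pan, 2L, max)[ks],
    core_mean = colMeans(core)[ks],
    core_min = apply(core, 2L, min)[ks],
    core_max = apply(core, 2L, max)[ks])
  rownames(out) <- NULL
  structure(out, n_orderings = n_orderings, n_replicates = n_replicates,
            seed = seed, class = c("saturation_curve", "data.frame"))
}
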