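## Windowed nucleotide diversity, Weir-Cockerham Fst, diversity-ratio sweep
## regions, top-quantile score tracks and the interval algebra that turns
## selected windows into merged sweep regions.

#' Per-site nucleotide diversity
#'
#' For a diploid site with `n` observed alleles of which `j` are the
#' alternate, returns the mean pairwise difference
#' `2 * j * (n - j) / (n * (n - 1))`. Sites with fewer than two non-missing
#' genotypes are unusable and return `NA`.
#'
#' @param dosages integer vector of alt dosages (0/1/2, NA missing) for one
#'   site.
#' @return per-site diversity (heterozygosity) in allele-pair units.
#' @examples
#' site_pi(c(1, 1))         # n = 4 alleles, j = 2 -> 2/3
#' site_pi(c(0, 0, 0))      # monomorphic -> 0
#' @export
site_pi <- function(dosages) {
  obs <- !is.na(dosages)
  if (sum(obs) < 2L) return(NA_real_)
  n <- 2 * sum(obs)
  j <- sum(dosages[obs])
  2 * j * (n - j) / (n * (n - 1))
}

## vectorised site pi over the rows of a dosage matrix
.site_pi_matrix <- function(g) {
  n_obs <- rowSums(!is.na(g))
  n <- 2 * n_obs
  j <- rowSums(g, na.rm = TRUE)
  pi <- ifelse(n_obs >= 2L, 2 * j * (n - j) / pmax(n * (n - 1), 1), NA_real_)
  list(pi = pi, usable = n_obs >= 2L)
}

#' Build a sliding-window grid over a genome layout
#'
#' Windows are 0-based half-open, start at 0 and advance by `step`;
#' chromosome-tail windows shorter than `window_size` are kept with their
#' true length.
#'
#' @param layout a [genome_layout()].
#' @param window_size window width in bp (default 100 kb).
#' @param step step size in bp (default 20 kb).
#' @return data.frame (`chrom`, `start`, `end`) of class `window_grid` with
#'   `window_size` and `step` attributes.
#' @export
make_windows <- function(layout, window_size = 1e5, step = 2e4) {
  stopifnot(inherits(layout, "genome_layout"), window_size >= 1, step >= 1)
  out <- do.call(rbind, lapply(names(layout), function(ch) {
    len <- layout[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len))
  }))
  rownames(out) <- NULL
  structure(out, window_size = window_size, step = step,
            class = c("window_grid", "data.frame"))
}

## sum `values` over sites falling in each half-open window of one chromosome
.window_sum <- function(pos_sorted, values_sorted, starts, ends) {
  cs <- c(0, cumsum(values_sorted))
  cnt_le <- function(x) findInterval(x, pos_sorted)
  cs[cnt_le(ends - 1L) + 1L] - cs[cnt_le(starts - 1L) + 1L]
}

.pop_samples <- function(groups, labels) {
  s <- names(groups)[groups %in% labels]
  if (!length(s)) stop("no accessions with group label(s): ",
                       paste(labels, collapse = ", "))
  s
}

#' Windowed nucleotide diversity per population
#'
#' Window pi is the sum of per-site diversities over variant sites in the
#' window divided by the window length in bp (monomorphic sites contribute
#' zero implicitly, the VCFtools `--window-pi` convention). Overlapping
#' windows each count shared sites.
#'
#' @param gt a [genotype_matrix()].
#' @param groups named character vector, accession -> group label.
#' @param windows a [make_windows()] grid.
#' @param pops named list; each element a vector of group labels pooled into
#'   one population (e.g. `list(landrace = "landrace",
#'   improved = c("GhImpUSO", "GhImpCHN"))`).
#' @return The window grid with, per population `x`, columns `pi_x`
#'   (per-bp diversity) and `n_x` (usable variant sites); class
#'   `window_track`.
#' @export
window_diversity <- function(gt, groups, windows, pops) {
  stopifnot(inherits(gt, "genotype_matrix"), is.list(pops),
            !is.null(names(pops)))
  out <- as.data.frame(windows)
  len <- out$end - out$start
  for (pn in names(pops)) {
    samp <- .pop_samples(groups, pops[[pn]])
    missing_samp <- setdiff(samp, gt$samples)
    if (length(missing_samp))
      stop("accessions absent from genotype matrix: ",
           paste(head(missing_samp, 5), collapse = ", "))
    sp <- .site_pi_matrix(gt$geno[, samp, drop = FALSE])
    pi_col <- n_col <- numeric(nrow(out))
    for (ch in unique(out$chrom)) {
      wi <- which(out$chrom == ch)
      si <- which(gt$chrom == ch & sp$usable)
      if (!length(si)) next
      o <- si[order(gt$pos[si])]
      pi_col[wi] <- .window_sum(gt$pos[o], sp$pi[o], out$start[wi],
                                out$end[wi])
      n_col[wi] <- .window_sum(gt$pos[o], rep(1, length(o)), out$start[wi],
                               out$end[wi])
    }
    out[[paste0("pi_", pn)]] <- pi_col / len
    out[[paste0("n_", pn)]] <- n_col
  }
  structure(out, window_size = attr(windows, "window_size"),
            step = attr(windows, "step"),
            class = c("window_track", "data.frame"))
}

## Weir & Cockerham (1984) two-population variance components per site.
## Returns a, b, c vectors; unusable sites (fewer than 2 non-missing
## genotypes in either population) are NA.
.wc_components <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  usable <- n1 >= 2L & n2 >= 2L
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  n_bar <- (n1 + n2) / 2
  n_c <- 2 * n_bar - (n1^2 + n2^2) / (2 * n_bar)
  p_bar <- (n1 * p1 + n2 * p2) / (2 * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / n_bar
  h_bar <- (n1 * h1 + n2 * h2) / (2 * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 / 2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 / 2 - h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  a[!usable] <- b[!usable] <- cc[!usable] <- NA_real_
  list(a = a, b = b, c = cc, usable = usable)
}

#' Weighted Weir-Cockerham Fst between two populations
#'
#' Per-site Weir & Cockerham (1984) variance components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals) are computed for two populations; the weighted estimate over
#' a window is `sum(a) / sum(a + b + c)` across usable sites. Sites with a
#' zero total component (e.g. both populations monomorphic for the same
#' allele) are excluded; windows with no usable site get `NA`.
#'
#' @param gt a [genotype_matrix()].
#' @param samples1,samples2 accession IDs of the two populations.
#' @param windows optional [make_windows()] grid; when omitted a single
#'   genome-wide weighted estimate is returned.
#' @return With `windows`: the grid plus columns `fst` and `n_fst_sites`
#'   (class `window_track`). Without: a single numeric value.
#' @export
weir_cockerham_fst <- function(gt, samples1, samples2, windows = NULL) {
  stopifnot(inherits(gt, "genotype_matrix"))
  g1 <- gt$geno[, samples1, drop = FALSE]
  g2 <- gt$geno[, samples2, drop = FALSE]
  wc <- .wc_components(g1, g2)
  tot <- wc$a + wc$b + wc$c
  use <- wc$usable & !is.na(tot) & tot != 0
  if (is.null(windows)) {
    if (!any(use)) return(NA_real_)
    return(sum(wc$a[use]) / sum(tot[use]))
  }
  out <- as.data.frame(windows)
  a_col <- t_col <- n_col <- numeric(nrow(out))
  for (ch in unique(out$chrom)) {
    wi <- which(out$chrom == ch)
    si <- which(gt$chrom == ch & use)
    if (!length(si)) next
    o <- si[order(gt$pos[si])]
    a_col[wi] <- .window_sum(gt$pos[o], wc$a[o], out$start[wi], out$end[wi])
    t_col[wi] <- .window_sum(gt$pos[o], tot[o], out$start[wi], out$end[wi])
    n_col[wi] <- .window_sum(gt$pos[o], rep(1, length(o)), out$start[wi],
                             out$end[wi])
  }
  out$fst <- ifelse(n_col > 0, a_col / t_col, NA_real_)
  out$n_fst_sites <- n_col
  structure(out, window_size = attr(windows, "window_size"),
            step = attr(windows, "step"),
            class = c("window_track", "data.frame"))
}

## ---- region sets ----------------------------------------------------------

#' Construct a region set
#'
#' Sorted genomic intervals (0-based half-open) with a provenance label.
#' Use [merge_regions()] to guarantee disjointness.
#'
#' @param chrom,start,end interval coordinates.
#' @param label provenance label (e.g. "domestication", "score_top").
#' @return data.frame of class `region_set`.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = "region") {
  if (length(start) && any(end <= start)) stop("region end must exceed start")
  d <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end))
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, label = label, class = c("region_set", "data.frame"))
}

.rs_to_gr <- function(rs) {
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(rs$start + 1, rs$end))
}

.gr_to_rs <- function(gr, label = "region") {
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
             label = label)
}

#' Merge nearby intervals of a region set
#'
#' Intervals separated by a gap of at most `gap_max` bp (half-open
#' convention: `start2 - end1`) are joined; the result is sorted and
#' disjoint. Idempotent.
#'
#' @param rs a [region_set()].
#' @param gap_max maximum gap joined (default 0 = merge only overlapping or
#'   bookended intervals).
#' @return The merged `region_set`.
#' @export
merge_regions <- function(rs, gap_max = 0) {
  if (nrow(rs) == 0L) return(rs)
  gr <- GenomicRanges::reduce(.rs_to_gr(rs), min.gapwidth = gap_max + 1)
  .gr_to_rs(gr, label = attr(rs, "label"))
}

#' Intersect two region sets
#'
#' Exact interval intersection in the half-open convention.
#'
#' @param a,b [region_set()] objects.
#' @param label label for the result (default "intersection").
#' @return A `region_set` of the overlaps.
#' @export
intersect_regions <- function(a, b, label = "intersection") {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(region_set(label = label))
  gr <- GenomicRanges::intersect(.rs_to_gr(a), .rs_to_gr(b),
                                 ignore.strand = TRUE)
  .gr_to_rs(gr, label = label)
}

#' Total span of a region set as a percentage of the genome
#'
#' @param rs a [region_set()] (merged; overlaps are counted once by merging
#'   internally first).
#' @param layout a [genome_layout()].
#' @param digits rounding digits for the percentage (default 1).
#' @return percentage of total genome length covered.
#' @export
region_fraction <- function(rs, layout, digits = 1) {
  rs <- merge_regions(rs, gap_max = 0)
  round(100 * sum(rs$end - rs$start) / sum(layout), digits)
}

#' Windowed diversity ratio
#'
#' Ratio of two population pi columns of a [window_diversity()] track.
#' Convention: denominator 0 with positive numerator gives `Inf` (complete
#' diversity loss, selected); windows with both pi equal to 0 give `NA`
#' (uninformative, never selected).
#'
#' @param track a `window_track` from [window_diversity()].
#' @param numerator,denominator population names used in `pops` (the earlier
#'   and later stage, e.g. "landrace" and "improved").
#' @return numeric vector of per-window ratios.
#' @export
window_ratio <- function(track, numerator, denominator) {
  pn <- paste0("pi_", numerator); pd <- paste0("pi_", denominator)
  if (!all(c(pn, pd) %in% names(track)))
    stop("unknown population name(s): ", numerator, ", ", denominator)
  num <- track[[pn]]; den <- track[[pd]]
  out <- num / den
  out[den == 0 & num > 0] <- Inf
  out[den == 0 & num == 0] <- NA_real_
  out
}

#' Candidate selection regions from a diversity-ratio threshold
#'
#' Windows whose pi ratio (earlier/later stage) reaches `ratio_min` are
#' selected and merged into regions; the default merge gap is the window
#' step, joining adjacent signals of a sliding grid.
#'
#' @param track a `window_track` from [window_diversity()].
#' @param numerator,denominator population names (see [window_ratio()]).
#' @param ratio_min selection threshold on the ratio (the study convention:
#'   15 for domestication, 2 for improvement scans).
#' @param gap_max merge gap in bp; defaults to the track's step size.
#' @param label region label (default "ratio").
#' @return A merged [region_set()] with attributes `n_windows` (selected
#'   windows) and `n_infinite` (windows selected through the Inf
#'   convention).
#' @export
ratio_regions <- function(track, numerator, denominator, ratio_min,
                          gap_max = NULL, label = "ratio") {
  r <- window_ratio(track, numerator, denominator)
  if (is.null(gap_max)) gap_max <- attr(track, "step")
  if (is.null(gap_max)) gap_max <- 0
  sel <- !is.na(r) & r >= ratio_min
  rs <- merge_regions(region_set(track$chrom[sel], track$start[sel],
                                 track$end[sel], label = label),
                      gap_max = gap_max)
  attr(rs, "n_windows") <- sum(sel)
  attr(rs, "n_infinite") <- sum(is.infinite(r[sel]))
  rs
}

#' Top-quantile score regions
#'
#' Selects the `ceiling(q * M)` highest-scoring of the `M` scored windows
#' (all ties at the cut included), then merges. Windows without a score are
#' ignored.
#'
#' @param track a `window_track` with a score column.
#' @param score_col name of the score column (default "score").
#' @param q upper quantile in (0, 1] (default 0.05, the top-5% convention).
#' @param gap_max merge gap in bp; defaults to the track step (or 0).
#' @param label region label (default "score_top").
#' @return A merged [region_set()]; attribute `threshold` holds the realized
#'   score cutoff.
#' @export
top_quantile_regions <- function(track, score_col = "score", q = 0.05,
                                 gap_max = NULL, label = "score_top") {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("`q` must lie in (0, 1]")
  s <- track[[score_col]]
  if (is.null(s)) stop("no column '", score_col, "' in track")
  scored <- which(!is.na(s))
  if (!length(scored)) stop("no scored windows")
  k <- ceiling(q * length(scored))
  thr <- sort(s[scored], decreasing = TRUE)[k]
  sel <- scored[s[scored] >= thr]
  if (is.null(gap_max)) gap_max <- attr(track, "step")
  if (is.null(gap_max)) gap_max <- 0
  rs <- merge_regions(region_set(track$chrom[sel], track$start[sel],
                                 track$end[sel], label = label),
                      gap_max = gap_max)
  attr(rs, "threshold") <- thr
  rs
}

#' Assign genes to regions by overlap
#'
#' A gene is assigned to a region when its span (default) or any exon
#' overlaps the region by at least 1 bp in the half-open convention
#' (bookended intervals do not overlap).
#'
#' @param regions a [region_set()].
#' @param gm a [gene_models()] object.
#' @param mode `"span"` (gene start-end) or `"exon"`.
#' @param layout optional [genome_layout()]; region chromosomes absent from
#'   it raise an error.
#' @return data.frame with one row per (region, gene) pair: `region_idx`
#'   (row in `regions`), `chrom`, `start`, `end`, `gene_id`.
#' @export
assign_genes_to_regions <- function(regions, gm, mode = c("span", "exon"),
                                    layout = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(gm, "gene_models"))
  if (!is.null(layout) && nrow(regions) &&
      !all(regions$chrom %in% names(layout)))
    stop("region chromosome absent from layout")
  empty <- data.frame(region_idx = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      gene_id = character())
  if (nrow(regions) == 0L || nrow(gm$genes) == 0L) return(empty)
  feat <- if (mode == "span") gm$genes else gm$exons
  fgr <- GenomicRanges::GRanges(feat$chrom,
                                IRanges::IRanges(feat$start + 1, feat$end))
  hits <- GenomicRanges::findOverlaps(.rs_to_gr(regions), fgr)
  if (!length(hits)) return(empty)
  ri <- S4Vectors::queryHits(hits)
  gi <- unique(data.frame(region_idx = ri,
                          gene_id = feat$gene_id[S4Vectors::subjectHits(hits)]))
  out <- data.frame(region_idx = gi$region_idx,
                    chrom = regions$chrom[gi$region_idx],
                    start = regions$start[gi$region_idx],
                    end = regions$end[gi$region_idx],
                    gene_id = gi$gene_id)
  out <- out[order(out$region_idx, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
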