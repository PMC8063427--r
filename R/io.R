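#' Genome layout: chromosome names and lengths
#'
#' A named vector of chromosome lengths (bp) used to validate windows,
#' regions and simulated coordinates.
#'
#' @param lengths named numeric vector, chromosome name -> length in bp.
#' @return A `genome_layout` object (named numeric vector).
#' @examples
#' genome_layout(c(A01 = 2e6, D01 = 1e6))
#' @export
genome_layout <- function(lengths) {
  if (!is.numeric(lengths) || length(lengths) < 1)
    stop("`lengths` must be a non-empty numeric vector")
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all chromosomes must be named")
  if (anyDuplicated(nm))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("chromosome lengths must be finite and >= 1")
  structure(as.numeric(round(lengths)), names = nm, class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x), " chromosome(s), ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

## ---- genotype matrix ------------------------------------------------------

#' Construct a genotype matrix object
#'
#' Container for diploid biallelic alt-allele dosages (0/1/2, NA = missing)
#' with site metadata. Positions are stored 0-based.
#'
#' @param geno integer matrix, sites x samples, values in \{0,1,2,NA\}.
#' @param chrom,pos character/integer vectors of site coordinates (0-based).
#' @param ref,alt allele strings; `alt` may hold comma-separated alleles for
#'   multi-allelic sites.
#' @param samples sample (accession) identifiers; defaults to `colnames(geno)`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(geno, chrom, pos, ref, alt, samples = colnames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- nrow(geno)
  stopifnot(length(chrom) == n_sites, length(pos) == n_sites,
            length(ref) == n_sites, length(alt) == n_sites)
  if (is.null(samples) || length(samples) != ncol(geno))
    stop("`samples` must name every column of `geno`")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  multi <- grepl(",", alt, fixed = TRUE)
  is_snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L
  indel_length <- ifelse(is_snp | multi, 0L, abs(nchar(alt) - nchar(ref)))
  colnames(geno) <- samples
  structure(list(
    geno = geno,
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    multiallelic = multi,
    variant_class = ifelse(is_snp | multi, "SNP", "InDel"),
    indel_length = as.integer(indel_length),
    samples = as.character(samples)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$geno), " sites x ", ncol(x$geno),
      " samples (", sum(x$multiallelic), " multi-allelic)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by site index
#' @param gt a `genotype_matrix`.
#' @param idx logical or integer site index.
#' @return The subset `genotype_matrix` (site order preserved).
#' @export
subset_sites <- function(gt, idx) {
  stopifnot(inherits(gt, "genotype_matrix"))
  gt$geno <- gt$geno[idx, , drop = FALSE]
  for (f in c("chrom", "pos", "ref", "alt", "multiallelic",
              "variant_class", "indel_length"))
    gt[[f]] <- gt[[f]][idx]
  gt
}

## GT string -> dosage. Half-calls (e.g. "./1") and alleles beyond the first
## alt read as missing; phased separators accepted.
.gt_to_dosage <- function(gt_chr) {
  gt_chr <- sub(":.*$", "", gt_chr)
  key <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  out <- unname(key[gt_chr])
  todo <- is.na(out) & !is.na(gt_chr)
  if (any(todo)) {
    parts <- strsplit(gt_chr[todo], "[/|]")
    out[todo] <- vapply(parts, function(a) {
      if (length(a) != 2L || any(a == ".") || !all(a %in% c("0", "1")))
        return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  out
}

#' Read diploid genotypes from a VCF file
#'
#' Genotypes are encoded as alt-allele dosages 0/1/2 with `NA` for missing
#' (`./.`) and half calls. Multi-allelic sites are retained but flagged so
#' the biallelic filter can drop them. VCF 1-based positions are converted
#' to the internal 0-based convention.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_subset optional character vector of sample IDs to keep;
#'   unknown IDs raise an error.
#' @param drop_scaffolds drop sites on chromosomes matching
#'   `scaffold_pattern` (unplaced scaffold sequences).
#' @param scaffold_pattern regular expression identifying scaffold names.
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path, sample_subset = NULL,
                               drop_scaffolds = FALSE,
                               scaffold_pattern = "(?i)^scaffold") {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L)
    stop("VCF '", path, "' contains no variant records")
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF '", path, "' has no genotype (GT) columns")
  samples <- colnames(gt_raw)[-1L]
  gts <- gt_raw[, -1L, drop = FALSE]
  dos <- matrix(.gt_to_dosage(as.vector(gts)), nrow = nrow(gts),
                dimnames = list(NULL, samples))
  gm <- genotype_matrix(dos,
                        chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]) - 1L,
                        ref = fix[, "REF"],
                        alt = fix[, "ALT"],
                        samples = samples)
  if (!is.null(sample_subset)) {
    unknown <- setdiff(sample_subset, samples)
    if (length(unknown))
      stop("samples not present in VCF: ", paste(unknown, collapse = ", "))
    gm$geno <- gm$geno[, sample_subset, drop = FALSE]
    gm$samples <- sample_subset
  }
  if (drop_scaffolds)
    gm <- subset_sites(gm, !grepl(scaffold_pattern, gm$chrom, perl = TRUE))
  gm
}

#' Write a genotype matrix to a minimal VCF 4.2 file
#'
#' Internal 0-based positions are emitted 1-based; dosages map back to
#' unphased GT strings.
#'
#' @param gt a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_matrix"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt$geno + 1L], nrow = nrow(gt$geno))
  gt_str[is.na(gt_str)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gt$samples), collapse = "\t"))
  body <- paste(gt$chrom, gt$pos + 1L, ".", gt$ref, gt$alt, ".", "PASS", ".",
                "GT", apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- gene models ----------------------------------------------------------

#' Construct a gene-model set
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `source` ("reference"/"non_reference"), `start`, `end` (0-based
#'   half-open gene span) and `exonic_length`.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open, non-overlapping within a gene).
#' @return A `gene_models` object.
#' @export
gene_models <- function(genes, exons) {
  need_g <- c("gene_id", "chrom", "strand", "source", "start", "end",
              "exonic_length")
  need_e <- c("gene_id", "chrom", "start", "end")
  stopifnot(all(need_g %in% names(genes)), all(need_e %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in gene table")
  if (nrow(exons) && !all(exons$gene_id %in% genes$gene_id))
    stop("exon rows refer to unknown genes")
  if (any(exons$end <= exons$start)) stop("exon end must exceed exon start")
  if (nrow(genes) && any(genes$exonic_length < 1))
    stop("total exon span must be >= 1 bp")
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ", nrow(x$exons),
      " exons\n", sep = "")
  invisible(x)
}

#' Read gene models (genes + exons) from a GFF3 file
#'
#' Exon features are grouped under their gene (directly or through an mRNA
#' parent); GFF3 1-based inclusive coordinates are converted to 0-based
#' half-open. Overlapping exon records of one gene are merged. A GFF3
#' `source` column equal to `"non_reference"` marks pan-genome genes absent
#' from the reference assembly.
#'
#' @param path GFF3 file.
#' @param layout optional [genome_layout()]; exons beyond a chromosome end
#'   raise an error.
#' @return A [gene_models()] object (empty if the file has no gene features).
#' @export
read_gff3_genes <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such GFF3 file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  empty <- gene_models(
    genes = data.frame(gene_id = character(), chrom = character(),
                       strand = character(), source = character(),
                       start = integer(), end = integer(),
                       exonic_length = integer()),
    exons = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer()))
  if (length(gr) == 0L) return(empty)
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  gene_idx <- which(type == "gene")
  if (!length(gene_idx)) return(empty)
  gene_ids <- ids[gene_idx]
  ## map feature ID -> owning gene (one mRNA/transcript level deep)
  parent_of <- rep(NA_character_, length(gr))
  pl <- gr$Parent
  has_parent <- lengths(pl) > 0L
  parent_of[has_parent] <- vapply(pl[has_parent], `[`, character(1), 1L)
  owner <- setNames(gene_ids, gene_ids)
  tx_idx <- which(!is.na(parent_of) & parent_of %in% gene_ids & type != "exon")
  owner[ids[tx_idx]] <- parent_of[tx_idx]
  exon_idx <- which(type == "exon")
  if (!length(exon_idx)) stop("GFF3 has gene features but no exons")
  ex_parent <- parent_of[exon_idx]
  ex_gene <- unname(owner[ex_parent])
  if (any(is.na(ex_gene)))
    stop("exon without a resolvable parent gene (parents: ",
         paste(unique(ex_parent[is.na(ex_gene)]), collapse = ", "), ")")
  ex <- data.frame(gene_id = ex_gene,
                   chrom = as.character(GenomicRanges::seqnames(gr))[exon_idx],
                   start = GenomicRanges::start(gr)[exon_idx] - 1L,
                   end = GenomicRanges::end(gr)[exon_idx])
  if (!is.null(layout)) {
    if (!all(ex$chrom %in% names(layout)))
      stop("exon chromosome absent from layout")
    if (any(ex$end > layout[ex$chrom]))
      stop("exon interval extends beyond chromosome end")
  }
  ## merge per-gene overlapping exon records
  ex <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }))
  rownames(ex) <- NULL
  src <- as.character(gr$source)[gene_idx]
  src <- ifelse(!is.na(src) & src == "non_reference", "non_reference",
                "reference")
  exlen <- tapply(ex$end - ex$start, ex$gene_id, sum)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gr))[gene_idx],
    strand = as.character(GenomicRanges::strand(gr))[gene_idx],
    source = src,
    start = GenomicRanges::start(gr)[gene_idx] - 1L,
    end = GenomicRanges::end(gr)[gene_idx],
    exonic_length = as.integer(exlen[gene_ids]))
  genes$strand[genes$strand == "*"] <- "."
  rownames(genes) <- NULL
  if (anyNA(genes$exonic_length))
    stop("gene(s) without exons: ",
         paste(genes$gene_id[is.na(genes$exonic_length)], collapse = ", "))
  gene_models(genes, ex)
}

#' Write gene models to GFF3
#' @param gm a [gene_models()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  g <- gm$genes; e <- gm$exons
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, paste(g$chrom[i], g$source[i], "gene", g$start[i] + 1L,
                            g$end[i], ".", ifelse(g$strand[i] == ".", ".",
                            g$strand[i]), ".",
                            paste0("ID=", g$gene_id[i]), sep = "\t"))
    ei <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ei)))
      lines <- c(lines, paste(ei$chrom[j], g$source[i], "exon",
                              ei$start[j] + 1L, ei$end[j], ".",
                              ifelse(g$strand[i] == ".", ".", g$strand[i]),
                              ".", paste0("Parent=", g$gene_id[i]),
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- PAV matrix and tabular inputs ---------------------------------------

#' Read / write a binary PAV matrix
#'
#' TSV format: first column `gene_id`, remaining columns one accession each,
#' cells 0/1. Writing then reading reproduces the matrix exactly.
#'
#' @param path TSV file.
#' @return `read_pav_matrix`: an integer matrix (genes x accessions) with
#'   dimnames.
#' @export
read_pav_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1L] != "gene_id") stop("first column must be 'gene_id'")
  if (anyDuplicated(d$gene_id)) stop("duplicated gene_id in PAV matrix")
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1)))
    stop("PAV matrix cells must all be 0 or 1")
  storage.mode(m) <- "integer"
  rownames(m) <- d$gene_id
  m
}

#' @param m integer matrix of 0/1 presence calls with gene rownames and
#'   accession colnames.
#' @rdname read_pav_matrix
#' @export
write_pav_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (anyNA(m) || !all(m %in% c(0L, 1L))) stop("cells must be 0 or 1")
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-window score track (e.g. XP-CLR output)
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `score` (0-based
#'   half-open windows; empty score cells are kept as `NA` and excluded from
#'   quantile computations downstream).
#' @param layout optional [genome_layout()] for bounds checking.
#' @return data.frame of class `window_track`.
#' @export
read_score_track <- function(path, layout = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "score")
  if (!all(need %in% names(d)))
    stop("score track needs columns: ", paste(need, collapse = ", "))
  d$score <- suppressWarnings(as.numeric(d$score))
  if (any(d$end <= d$start)) stop("window end must exceed start")
  if (!is.null(layout)) {
    if (!all(d$chrom %in% names(layout)))
      stop("window chromosome absent from layout")
    if (any(d$end > layout[d$chrom]))
      stop("window extends beyond chromosome end")
  }
  class(d) <- c("window_track", "data.frame")
  d
}

#' Read accession group labels
#' @param path two-column TSV: `accession`, `group`.
#' @return named character vector, accession -> group.
#' @export
read_group_labels <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "group") %in% names(d)))
    stop("group table needs columns 'accession' and 'group'")
  if (anyDuplicated(d$accession)) stop("duplicated accession in group table")
  setNames(d$group, d$accession)
}

#' Read QTL intervals
#' @param path TSV with columns `qtl_id`, `trait`, `chrom`, `start`, `end`
#'   (0-based half-open) and `origin` (`snpQTL`/`cnvQTL`).
#' @return data.frame of QTL intervals.
#' @export
read_qtl_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("qtl_id", "trait", "chrom", "start", "end", "origin")
  if (!all(need %in% names(d)))
    stop("QTL table needs columns: ", paste(need, collapse = ", "))
  if (any(d$end <= d$start)) stop("QTL end must exceed start")
  d
}

#' Read a per-accession per-gene exon coverage table
#' @param path TSV with columns `accession`, `gene_id`,
#'   `exonic_bases_covered`, `exonic_bases_total`.
#' @return data.frame.
#' @export
read_coverage_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "gene_id", "exonic_bases_covered",
            "exonic_bases_total")
  if (!all(need %in% names(d)))
    stop("coverage table needs columns: ", paste(need, collapse = ", "))
  d
}

#' Write a region set as BED (0-based half-open)
#' @param regions a [region_set()] or data.frame with `chrom`, `start`, `end`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  d <- as.data.frame(regions)[, c("chrom", "start", "end")]
  write.table(format(d, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
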