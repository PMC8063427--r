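test_that("site_pi equals the brute-force mean pairwise difference", {
  expect_equal(site_pi(c(1, 1)), 2 / 3, tolerance = 1e-12)  # n=4, j=2
  expect_equal(site_pi(c(0, 0, 0)), 0)                       # monomorphic
  expect_equal(site_pi(c(2, 2, 2)), 0)                       # j = n symmetry
  expect_true(is.na(site_pi(c(1, NA))))                      # < 2 genotypes
  set.seed(11)
  for (i in 1:50) {
    d <- sample(c(0:2, NA), sample(2:12, 1), replace = TRUE)
    expect_equal(site_pi(d), oracle_site_pi(d), tolerance = 1e-12)
  }
})

test_that("window pi matches a brute-force oracle on overlapping windows", {
  set.seed(5)
  n_sites <- 10; n_samp <- 8
  d <- matrix(sample(c(0:2, NA), n_sites * n_samp, TRUE), n_sites)
  pos <- sort(sample(0:999, n_sites))
  gt <- toy_gt(d, pos = pos)
  groups <- setNames(rep("landrace", n_samp), gt$samples)
  w <- make_windows(genome_layout(c(A01 = 1000)), window_size = 400,
                    step = 150)
  tr <- window_diversity(gt, groups, w, pops = list(landrace = "landrace"))
  for (k in seq_len(nrow(w))) {
    in_w <- pos >= w$start[k] & pos < w$end[k]
    vals <- vapply(which(in_w), function(i) oracle_site_pi(d[i, ]),
                   numeric(1))
    vals <- vals[!is.na(vals)]
    expect_equal(tr$pi_landrace[k],
                 sum(vals) / (w$end[k] - w$start[k]), tolerance = 1e-12)
  }
  # a single site with pi 2/3 in a 100 kb window
  gt1 <- toy_gt(matrix(c(1L, 1L), 1), pos = 5L)
  w1 <- make_windows(genome_layout(c(A01 = 1e5)), 1e5, 1e5)
  tr1 <- window_diversity(gt1, setNames(rep("g", 2), gt1$samples), w1,
                          pops = list(g = "g"))
  expect_equal(tr1$pi_g, (2 / 3) / 1e5, tolerance = 1e-12)
  # empty window
  expect_equal(window_diversity(gt1, setNames(rep("g", 2), gt1$samples),
                                make_windows(genome_layout(c(B01 = 1e5)),
                                             1e5, 1e5),
                                pops = list(g = "g"))$pi_g, 0)
})

test_that("chromosome-tail windows keep their true length as denominator", {
  w <- make_windows(genome_layout(c(A01 = 250000)), 1e5, 1e5)
  expect_equal(w$end - w$start, c(1e5, 1e5, 5e4))
  gt <- toy_gt(matrix(c(1L, 1L), 1), pos = 210000L)
  tr <- window_diversity(gt, setNames(rep("g", 2), gt$samples), w,
                         pops = list(g = "g"))
  expect_equal(tr$pi_g[3], (2 / 3) / 5e4, tolerance = 1e-12)
})

test_that("Weir-Cockerham Fst is 1 on fixed differences and NA when empty", {
  gt <- toy_gt(cbind(matrix(0L, 3, 5), matrix(2L, 3, 5)))
  s1 <- gt$samples[1:5]; s2 <- gt$samples[6:10]
  expect_equal(weir_cockerham_fst(gt, s1, s2), 1)
  gt0 <- toy_gt(matrix(0L, 3, 10))   # both monomorphic, same allele: 0/0
  expect_true(is.na(weir_cockerham_fst(gt0, s1, s2)))
})

test_that("Fst agrees with the direct variance-component oracle", {
  # toy site: pop1 dosages (0,0,1), pop2 (1,2,2)
  d1 <- c(0L, 0L, 1L); d2 <- c(1L, 2L, 2L)
  gt <- toy_gt(matrix(c(d1, d2), 1))
  comp <- oracle_wc_site(d1, d2)
  expect_equal(weir_cockerham_fst(gt, gt$samples[1:3], gt$samples[4:6]),
               comp["a"] / sum(comp), ignore_attr = TRUE,
               tolerance = 1e-10)
  # windowed weighted estimate over random sites
  set.seed(21)
  n_sites <- 40
  d <- matrix(sample(c(0:2, NA), n_sites * 12, TRUE,
                     prob = c(0.4, 0.2, 0.3, 0.1)), n_sites)
  gt <- toy_gt(d, pos = seq_len(n_sites) * 10L)
  s1 <- gt$samples[1:6]; s2 <- gt$samples[7:12]
  w <- make_windows(genome_layout(c(A01 = 500)), 200, 100)
  tr <- weir_cockerham_fst(gt, s1, s2, w)
  for (k in seq_len(nrow(w))) {
    in_w <- gt$pos >= w$start[k] & gt$pos < w$end[k]
    acc <- c(0, 0)
    for (i in which(in_w)) {
      x1 <- d[i, 1:6]; x2 <- d[i, 7:12]
      if (sum(!is.na(x1)) < 2 || sum(!is.na(x2)) < 2) next
      comp <- oracle_wc_site(x1, x2)
      if (sum(comp) == 0) next
      acc <- acc + c(comp["a"], sum(comp))
    }
    if (acc[2] == 0) expect_true(is.na(tr$fst[k]))
    else expect_equal(tr$fst[k], unname(acc[1] / acc[2]),
                      tolerance = 1e-10)
  }
  ok <- !is.na(tr$fst)
  expect_true(all(tr$fst[ok] >= -0.2 & tr$fst[ok] <= 1))
})

test_that("ratio selection applies thresholds and limit conventions", {
  tr <- structure(
    data.frame(chrom = "A01", start = c(0, 1e5, 2e5, 3e5),
               end = c(1e5, 2e5, 3e5, 4e5),
               pi_landrace = c(1e-3, 5e-5, 1e-3, 0),
               pi_improved = c(5e-5, 5e-5, 0, 0)),
    step = 1e5, class = c("window_track", "data.frame"))
  r <- window_ratio(tr, "landrace", "improved")
  expect_equal(r[1], 20)                  # 20 >= 15: selected
  expect_equal(r[2], 1)                   # equal diversity: not selected
  expect_true(is.infinite(r[3]))          # zero denominator: selected
  expect_true(is.na(r[4]))                # both zero: excluded
  rs <- ratio_regions(tr, "landrace", "improved", ratio_min = 15,
                      gap_max = 0)
  expect_equal(as.data.frame(rs),
               data.frame(chrom = "A01", start = c(0, 2e5),
                          end = c(1e5, 3e5)), ignore_attr = TRUE)
  expect_equal(attr(rs, "n_infinite"), 1L)
  # the default merge gap (the step size) joins adjacent signals
  rs2 <- ratio_regions(tr, "landrace", "improved", ratio_min = 15)
  expect_equal(as.data.frame(rs2),
               data.frame(chrom = "A01", start = 0, end = 3e5),
               ignore_attr = TRUE)
  expect_error(window_ratio(tr, "landrace", "nope"), "unknown population")
})

test_that("top-quantile selection includes all ties at the cut", {
  tr <- structure(
    data.frame(chrom = "A01", start = (0:99) * 1e5, end = (1:100) * 1e5,
               score = 1:100),
    step = 1e5, class = c("window_track", "data.frame"))
  rs <- top_quantile_regions(tr, q = 0.05, gap_max = 0)
  expect_equal(c(rs$start, rs$end), c(95e5, 100e5))  # windows scored 96..100
  expect_equal(attr(rs, "threshold"), 96)
  tr$score <- rep(7, 100)
  expect_equal(as.data.frame(top_quantile_regions(tr, q = 0.05, gap_max = 0)),
               data.frame(chrom = "A01", start = 0, end = 1e7),
               ignore_attr = TRUE)                   # all 100 tie in
  tr$score <- 1:100
  expect_equal(nrow(top_quantile_regions(tr, q = 1, gap_max = -1)), 100L)
  expect_error(top_quantile_regions(tr, q = 0), "0, 1")
  expect_error(top_quantile_regions(tr, q = 1.2), "0, 1")
})

test_that("interval intersection and merging follow half-open arithmetic", {
  a <- region_set("A01", 0, 1e5)
  b <- region_set("A01", 5e4, 1.5e5)
  expect_equal(as.data.frame(intersect_regions(a, b)),
               data.frame(chrom = "A01", start = 5e4, end = 1e5),
               ignore_attr = TRUE)
  m <- merge_regions(region_set("A01", c(0, 2e4), c(1e5, 1.2e5)))
  expect_equal(as.data.frame(m),
               data.frame(chrom = "A01", start = 0, end = 1.2e5),
               ignore_attr = TRUE)
  # disjoint with gap > gap_max stays unchanged
  d <- region_set("A01", c(0, 2e5), c(1e5, 3e5))
  expect_equal(nrow(merge_regions(d, gap_max = 99999)), 2L)
  expect_equal(nrow(merge_regions(d, gap_max = 1e5)), 1L)
})

test_that("region algebra is idempotent, associative, sorted and disjoint", {
  set.seed(3)
  rand_rs <- function() {
    s <- sample(0:500, 8) * 100
    region_set(sample(c("A01", "D01"), 8, TRUE), s,
               s + sample(1:30, 8) * 100)
  }
  for (i in 1:20) {
    a <- rand_rs(); b <- rand_rs(); cc <- rand_rs()
    ma <- merge_regions(a, 50)
    expect_identical(as.data.frame(merge_regions(ma, 50)),
                     as.data.frame(ma))              # idempotent
    lhs <- intersect_regions(intersect_regions(a, b), cc)
    rhs <- intersect_regions(a, intersect_regions(b, cc))
    expect_identical(as.data.frame(lhs), as.data.frame(rhs))  # associative
    expect_true(all(diff(ma$start[ma$chrom == "A01"]) > 0))
    for (ch in unique(ma$chrom)) {
      mm <- ma[ma$chrom == ch, ]
      if (nrow(mm) > 1)
        expect_true(all(mm$start[-1] > mm$end[-nrow(mm)]))    # disjoint
    }
  }
})

test_that("genes attach to regions by >= 1 bp half-open overlap", {
  gm <- gene_models(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "A01",
                       strand = "+", source = "reference",
                       start = c(10, 20), end = c(20, 30),
                       exonic_length = c(10, 10)),
    exons = data.frame(gene_id = c("g1", "g2"), chrom = "A01",
                       start = c(10, 20), end = c(20, 30)))
  rs <- region_set("A01", 15, 40)
  hits <- assign_genes_to_regions(rs, gm)
  expect_setequal(hits$gene_id, c("g1", "g2"))
  # bookended half-open intervals [10,20) vs [20,30) do not overlap
  rs2 <- region_set("A01", 20, 30)
  expect_equal(assign_genes_to_regions(rs2, gm)$gene_id, "g2")
  expect_equal(nrow(assign_genes_to_regions(region_set(), gm)), 0L)
  expect_error(assign_genes_to_regions(rs, gm, layout =
                                         genome_layout(c(Z = 100))),
               "absent from layout")
})

test_that("region_fraction reports merged span over genome length", {
  lay <- genome_layout(c(A = 1000))
  rs <- region_set("A", c(0, 100), c(200, 300))  # overlap counted once
  expect_equal(region_fraction(rs, lay), 30)
})
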