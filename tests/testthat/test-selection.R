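test_that("two-sided Fisher p matches the hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(8, 2, 1, 9), 1012 / 184756,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  # swapping rows leaves p unchanged
  set.seed(2)
  for (i in 1:25) {
    t4 <- sample(0:15, 4, TRUE)
    if (sum(t4) == 0) next
    expect_equal(fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4]),
                 fisher_exact_2x2(t4[3], t4[4], t4[1], t4[2]),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("BH q-values follow the step-up hand calculation", {
  expect_equal(bh_fdr(0.04), 0.04)                        # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3)) # all pull to 0.03
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))           # monotone in p
})

test_that("stage selection verdicts follow FDR and fold-change rules", {
  # gene 1: landrace 180/182 vs GhImpUSO 10/206 -> unfavorable (FC ~ 20.4)
  # gene 2: identical frequencies -> none
  # gene 3: landrace 5/182 vs GhImpUSO 150/206 -> favorable (FC ~ 0.038)
  # gene 4: absent everywhere -> untested
  tp <- toy_presence(c(180, 91, 5, 0), 182,
                     c(10, 103, 150, 0), 206,
                     c(10, 103, 150, 0), 206)
  fr <- presence_frequency(tp$presence, tp$groups)
  sel <- classify_stage_selection(fr, "domestication")
  expect_equal(sel$verdict, c("unfavorable", "none", "favorable", "none"))
  expect_equal(sel$tested, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sel$fold_change[1], (180 / 182) / (10 / 206))
  expect_equal(sel$fisher_p[1], fisher_exact_2x2(180, 2, 10, 196),
               tolerance = 1e-12)
  expect_true(sel$fdr_q[1] < 0.001 && sel$fdr_q[3] < 0.001)
  expect_true(is.na(sel$fisher_p[4]))
})

test_that("zero later-stage frequency yields an infinite fold change", {
  tp <- toy_presence(c(150, 0), 182, c(0, 0), 206, c(0, 0), 206)
  sel <- classify_stage_selection(presence_frequency(tp$presence,
                                                     tp$groups),
                                  "domestication")
  expect_true(is.infinite(sel$fold_change[1]))
  expect_equal(sel$verdict[1], "unfavorable")   # Inf qualifies as > 2
})

test_that("trajectory chains are strict and mutually exclusive", {
  fr <- data.frame(gene_id = paste0("g", 1:6),
                   freq_landrace = c(0.1, 0.8, 0.1, 0.4, 0.5, 0.0),
                   freq_GhImpUSO = c(0.4, 0.4, 0.6, 0.2, 0.5, 0.0),
                   freq_GhImpCHN = c(0.8, 0.1, 0.2, 0.6, 0.9, 0.0))
  traj <- classify_trajectory(fr)
  expect_equal(unname(traj),
               c("favorable_gain", "unfavorable_loss", "favorable_loss",
                 "unfavorable_gain", "none", "none"))
  # property: at most one strict chain can hold
  set.seed(6)
  for (i in 1:100) {
    f <- round(runif(3), 2)
    chains <- c(f[3] > f[2] && f[2] > f[1],
                f[2] > f[1] && f[3] < f[2],
                f[1] > f[2] && f[3] > f[2],
                f[3] < f[2] && f[2] < f[1])
    expect_lte(sum(chains), 1L)
    got <- classify_trajectory(data.frame(gene_id = "g",
                                          freq_landrace = f[1],
                                          freq_GhImpUSO = f[2],
                                          freq_GhImpCHN = f[3]))
    expect_equal(unname(got != "none"), any(chains))
  }
})

test_that("Bonferroni thresholds reproduce printed GWAS cutoffs", {
  expect_equal(signif(bonferroni_threshold(0.05, 2291437)$threshold, 3),
               2.18e-8)
  b <- bonferroni_threshold(0.05, 1904926)
  expect_equal(signif(b$threshold, 3), 2.62e-8)
  expect_equal(round(b$neg_log10, 1), 7.6)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  expect_error(bonferroni_threshold(0, 10), "\\(0, 1\\]")
})

test_that("PAV-SNP association flags co-segregating SNPs only", {
  set.seed(8)
  n <- 100
  pres <- setNames(rep(c(1L, 0L), each = n / 2), sprintf("S%03d", 1:n))
  # SNP 1 co-segregates perfectly; the rest are independent noise
  d <- rbind(matrix(rep(c(2L, 0L), each = n / 2), 1),
             matrix(rbinom(50 * n, 2, 0.3), 50))
  gt <- genotype_matrix(d, chrom = rep("A01", 51),
                        pos = seq_len(51) * 1000L, ref = rep("A", 51),
                        alt = rep("T", 51), samples = names(pres))
  res <- pav_snp_association(pres, gt, alpha = 0.05)
  expect_equal(res$threshold, 0.05 / 51)
  expect_true(1000L %in% res$significant$pos)   # the planted SNP
  # independent SNPs essentially never pass Bonferroni
  expect_lte(nrow(res$significant), 2L)
  expect_error(pav_snp_association(setNames(rep(1L, n), names(pres)), gt),
               "constant")
})

test_that("significant positions overlap QTLs half-open", {
  qtls <- data.frame(qtl_id = c("q1", "q2"), trait = c("FL", "BW"),
                     chrom = "A01", start = c(500, 3000),
                     end = c(2000, 4000), origin = "snpQTL")
  pos <- data.frame(chrom = "A01", pos = c(1000, 2000, 3999))
  ov <- overlap_with_qtl(pos, qtls)
  expect_equal(ov$qtl_id, c("q1", "q2"))
  expect_equal(ov$pos, c(1000, 3999))           # 2000 misses [500, 2000)
  expect_equal(nrow(overlap_with_qtl(pos, qtls[0, ])), 0L)
})

test_that("rank-sum test enumerates exactly on small samples", {
  ph <- c(1, 2, 3, 4, 5, 6)
  pres <- c(1, 1, 1, 0, 0, 0)
  expect_equal(rank_sum_presence_test(ph, pres), 0.1)   # 2/20 assignments
  # label exchange leaves p unchanged
  expect_equal(rank_sum_presence_test(ph, 1 - pres), 0.1)
  expect_equal(rank_sum_presence_test(rep(5, 6), pres), 1)
  expect_error(rank_sum_presence_test(ph, c(1, 0, 0, 0, 0, 0)),
               "at least 2")
})
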