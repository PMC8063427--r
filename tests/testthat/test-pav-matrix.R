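test_that("presence calling is strict at the 0.8 boundary with a gray zone", {
  out <- call_gene_presence(c(85, 80, 50, 20, 10), 100)
  expect_equal(out$present, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$gray_zone, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_error(call_gene_presence(1, 0), "positive")
  expect_error(call_gene_presence(5, 4), "\\[0, total\\]")
  # monotone in the covered fraction
  fr <- sort(runif(50))
  pres <- call_gene_presence(round(fr * 1e6), 1e6)$present
  expect_true(all(diff(as.integer(pres)) >= 0))
})

test_that("build_pav_matrix calls the full grid and flags depth classes", {
  cov <- expand.grid(accession = c("a1", "a2"), gene_id = c("g1", "g2"),
                     stringsAsFactors = FALSE)
  cov$exonic_bases_total <- 100
  cov$exonic_bases_covered <- c(100, 100, 0, 81)
  depth <- data.frame(accession = c("a1", "a2"), mean_depth = c(20, 3))
  pav <- build_pav_matrix(cov, depth)
  expect_equal(pav$presence["g1", ], c(a1 = 1L, a2 = 1L))
  expect_equal(pav$presence["g2", ], c(a1 = 0L, a2 = 1L))
  expect_equal(unname(pav$depth_class), c("high", "low"))
  expect_error(build_pav_matrix(cov[-1, ], depth), "missing coverage row")
  cov$exonic_bases_covered <- c(100, 100, 100, 100)
  expect_true(all(build_pav_matrix(cov, depth)$presence == 1L))
  cov$exonic_bases_covered <- 0
  expect_true(all(build_pav_matrix(cov, depth)$presence == 0L))
})

test_that("singletons are genes confined to low-depth accessions", {
  m <- matrix(c(1L, 1L, 0L,   # g1: low-depth only -> singleton
                0L, 1L, 1L,   # g2: reaches a high-depth accession
                0L, 0L, 1L),  # g3: one high-depth accession (cloud, not
              nrow = 3, byrow = TRUE,                      # singleton)
              dimnames = list(c("g1", "g2", "g3"), c("a1", "a2", "a3")))
  dc <- c(a1 = "low", a2 = "low", a3 = "high")
  pav <- pav_matrix(m, depth_class = dc)
  expect_equal(detect_singletons(pav), "g1")
  # no low-depth accessions: no singletons
  pav2 <- pav_matrix(m, depth_class = c(a1 = "high", a2 = "high",
                                        a3 = "high"))
  expect_equal(detect_singletons(pav2), character(0))
})

test_that("pan-gene classes reproduce the boundary arithmetic", {
  counts <- setNames(0:1020, paste0("g", 0:1020))
  cls <- classify_pan_genes(counts, 1020, class_thresholds(0.97, 0.01))
  cl <- setNames(cls$classes$class, cls$classes$presence_count)
  expect_equal(cls$softcore_min_count, 990L)  # ceil(0.97 * 1020)
  expect_equal(cls$cloud_max_count, 10L)      # floor(0.01 * 1020)
  expect_equal(unname(cl["1020"]), "core")
  expect_equal(unname(cl[c("990", "1019")]), rep("softcore", 2))
  expect_equal(unname(cl[c("11", "989")]), rep("shell", 2))
  expect_equal(unname(cl[c("1", "10")]), rep("cloud", 2))
  expect_equal(unname(cl["0"]), "absent")
  # smaller panel with the 2% cloud convention
  cls2 <- classify_pan_genes(setNames(1:177, paste0("g", 1:177)), 177,
                             class_thresholds(0.97, 0.02))
  cl2 <- setNames(cls2$classes$class, cls2$classes$presence_count)
  expect_equal(unname(cl2["3"]), "cloud")     # floor(0.02 * 177) = 3
  expect_equal(unname(cl2["4"]), "shell")
  expect_equal(unname(cl2["172"]), "softcore")
  expect_error(classify_pan_genes(counts, 0), "positive")
  expect_error(classify_pan_genes(c(g = 5L), 4), "\\[0, N\\]")
})

test_that("classification from a pav_matrix uses high-depth accessions", {
  m <- matrix(c(1L, 1L, 1L, 1L,
                1L, 1L, 1L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("a", 1:4)))
  dc <- c(a1 = "high", a2 = "high", a3 = "high", a4 = "low")
  cls <- classify_pan_genes(pav_matrix(m, depth_class = dc))
  # both genes present in all 3 high-depth accessions -> core
  expect_equal(cls$classes$class, c("core", "core"))
  expect_equal(cls$n_accessions, 3L)
})

test_that("category summary computes percentages over the pan total", {
  s <- category_summary(c(softcore = 59, shell = 38, cloud = 124),
                        total_pan_genes = 1000)
  expect_equal(s$table$pct, c(5.9, 3.8, 12.4))
  expect_equal(s$variable_count, 221)
  expect_error(category_summary(c(core = 10), total_pan_genes = 5),
               "smaller than")
  expect_error(category_summary(c(5, 3), 100), "named")
})

test_that("saturation curves are ordering-invariant at k = N", {
  m <- matrix(c(1L, 1L, 1L,    # g1 in A, B, C
                1L, 0L, 0L,    # g2 in A
                0L, 1L, 0L),   # g3 in B
              nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B", "C")))
  sat <- saturation_curve(m, n_orderings = 20, n_replicates = 1, seed = 2)
  at_n <- sat[sat$k == 3, ]
  expect_equal(c(at_n$pan_min, at_n$pan_max), c(3, 3))
  expect_equal(c(at_n$core_min, at_n$core_max), c(1, 1))
  # identical gene sets give flat curves
  flat <- saturation_curve(matrix(1L, 4, 5, dimnames = list(paste0("g", 1:4),
                                                            paste0("a", 1:5))),
                           n_orderings = 5, n_replicates = 1, seed = 1)
  expect_true(all(flat$pan_mean == 4) && all(flat$core_mean == 4))
  expect_error(saturation_curve(m[, 1, drop = FALSE]), "at least 2")
})

test_that("pan counts never fall and core counts never rise along k", {
  set.seed(13)
  for (i in 1:30) {
    m <- matrix(rbinom(20 * 8, 1, runif(1, 0.2, 0.9)), 20, 8,
                dimnames = list(paste0("g", 1:20), paste0("a", 1:8)))
    sat <- saturation_curve(m, n_orderings = 6, n_replicates = 1, seed = i)
    expect_true(all(diff(sat$pan_min) >= 0) && all(diff(sat$pan_max) >= 0))
    expect_true(all(diff(sat$core_min) <= 0) && all(diff(sat$core_max) <= 0))
    expect_true(all(sat$pan_min >= sat$core_min))
    expect_true(all(sat$pan_mean >= sat$core_mean))
    # k = N equals the full-matrix union / intersection
    expect_equal(sat$pan_mean[nrow(sat)], sum(rowSums(m) > 0))
    expect_equal(sat$core_mean[nrow(sat)], sum(rowSums(m) == 8))
  }
})
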