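# Small in-code fixtures shared across test files.

# genotype matrix from a plain dosage matrix (sites x samples)
toy_gt <- function(d, chrom = "A01", pos = seq_len(nrow(d)) * 100L,
                   ref = "A", alt = "T") {
  d <- as.matrix(d)
  colnames(d) <- sprintf("S%02d", seq_len(ncol(d)))
  genotype_matrix(d, chrom = rep(chrom, length.out = nrow(d)), pos = pos,
                  ref = rep(ref, length.out = nrow(d)),
                  alt = rep(alt, length.out = nrow(d)))
}

# brute-force per-site diversity: mean pairwise difference over all allele
# pairs (independent of the closed-form implementation)
oracle_site_pi <- function(dosages) {
  dosages <- dosages[!is.na(dosages)]
  if (length(dosages) < 2) return(NA_real_)
  alleles <- unlist(lapply(dosages, function(d) c(rep(1, d), rep(0, 2 - d))))
  pairs <- utils::combn(length(alleles), 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# scalar Weir & Cockerham (1984) variance components for one site,
# evaluated directly from the 1984 two-population formulas
oracle_wc_site <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  n1 <- length(d1); n2 <- length(d2); r <- 2
  p1 <- sum(d1) / (2 * n1); p2 <- sum(d2) / (2 * n2)
  h1 <- mean(d1 == 1); h2 <- mean(d2 == 1)
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# presence matrix with exact per-group presence counts, for frequency tests
toy_presence <- function(counts_landrace, n_landrace,
                         counts_uso, n_uso, counts_chn, n_chn) {
  stopifnot(length(counts_landrace) == length(counts_uso),
            length(counts_uso) == length(counts_chn))
  acc <- c(sprintf("L%03d", seq_len(n_landrace)),
           sprintf("U%03d", seq_len(n_uso)),
           sprintf("C%03d", seq_len(n_chn)))
  groups <- setNames(rep(c("landrace", "GhImpUSO", "GhImpCHN"),
                         c(n_landrace, n_uso, n_chn)), acc)
  ng <- length(counts_landrace)
  m <- matrix(0L, ng, length(acc),
              dimnames = list(sprintf("gene%02d", seq_len(ng)), acc))
  for (i in seq_len(ng)) {
    m[i, seq_len(counts_landrace[i])] <- 1L
    m[i, n_landrace + seq_len(counts_uso[i])] <- 1L
    m[i, n_landrace + n_uso + seq_len(counts_chn[i])] <- 1L
  }
  list(presence = m, groups = groups)
}
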