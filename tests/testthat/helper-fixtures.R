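# shared fixture builders; everything is generated in code at test time

toy_snp <- function(id = "rs0001", major = "C", minor = "T", chrom = "chr1",
                    pos = 1000, build = "GRCh37") {
  snp_def(id, chrom, pos, major, minor, build = build)
}

# a small hand-built dataset: 2 SNPs, case/control, one missing genotype
toy_dataset <- function() {
  s1 <- toy_snp("rs0001", "C", "T")
  s2 <- toy_snp("rs0002", "A", "G", pos = 2000)
  samples <- data.frame(
    sample_id = paste0("S", 1:8),
    group = rep(c("case", "control"), each = 4),
    age = c(61, 45, 70, 58, 50, 44, 39, 47),
    stringsAsFactors = FALSE)
  g <- cbind(
    rs0001 = c("CC", "CT", "TC", "TT", "CC", "CC", "CT", NA),
    rs0002 = c("AA", "AG", "GG", "AA", "AG", "AA", NA, "GG"))
  rownames(g) <- samples$sample_id
  genotype_dataset(samples, g, list(s1, s2), build = "GRCh37")
}

# genotype counts with arbitrary cells
toy_counts <- function(case = c(30, 40, 30), control = c(25, 50, 25),
                       snp = toy_snp()) {
  genotype_counts(snp, rbind(case = case, control = control))
}

# independent oracle for the odds ratio with column-2 group as outcome:
# ref row (a1, a2), exposure row (b1, b2)
oracle_or_col2 <- function(a1, a2, b1, b2) (b2 * a1) / (b1 * a2)

# independent G-test oracle via expected counts from margins
oracle_g_test <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  g <- 2 * sum(ifelse(m > 0, m * log(m / e), 0))
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(g = g, p = pchisq(g, df, lower.tail = FALSE))
}

# independent HWE chi-square oracle
oracle_hwe <- function(cc) {
  n <- sum(cc)
  p <- (2 * cc[1] + cc[2]) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi <- sum((cc - e)^2 / e)
  list(chi2 = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# brute-force haplotype counting when phase is known (audit channel)
oracle_hap_freqs_from_truth <- function(dataset) {
  h <- attr(dataset, "true_haplotypes")
  tabulate(c(h[, 1], h[, 2]), nbins = 4) / (2 * nrow(h))
}
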