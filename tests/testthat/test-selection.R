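test_that("compute_de matches the Welch-on-log2 definition", {
  set.seed(42)
  vals <- matrix(2^(rnorm(40, mean = 4)), nrow = 2)
  rownames(vals) <- c("g1", "g2")
  samples <- data.frame(sample_id = paste0("S", 1:20),
                        group = rep(c("tumor", "normal"), each = 10),
                        stringsAsFactors = FALSE)
  de <- compute_de(vals, "tumor", "normal", samples = samples)
  la <- log2(vals[, 1:10] + 1); lb <- log2(vals[, 11:20] + 1)
  expect_equal(de$log2fc, unname(rowMeans(la) - rowMeans(lb)))
  expect_equal(de$p_value[1], t.test(la[1, ], lb[1, ])$p.value)
  # antisymmetry under label swap
  de_sw <- compute_de(vals, "normal", "tumor", samples = samples)
  expect_equal(de_sw$log2fc, -de$log2fc)
  expect_equal(de_sw$p_value, de$p_value)
})

test_that("identical groups give log2fc 0 and p 1; small groups error", {
  vals <- matrix(rep(c(8, 2), each = 6), nrow = 2, byrow = TRUE)
  samples <- data.frame(sample_id = paste0("S", 1:6),
                        group = rep(c("a", "b"), each = 3))
  de <- compute_de(vals, "a", "b", samples = samples)
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p_value, c(1, 1))
  samples1 <- data.frame(sample_id = paste0("S", 1:6),
                         group = c("a", rep("b", 5)))
  expect_error(compute_de(vals, "a", "b", samples = samples1), ">= 2")
  expect_error(compute_de(-vals, "a", "b", samples = samples), ">= 0")
})

test_that("DE filter is linear fold change with strict p cut", {
  de <- data.frame(
    gene = c("AQP4-AS1", "weak", "MEG3", "flat", "late"),
    log2fc = c(0.87, 0.50, -1.93, 0.05, 2.00),
    p_value = c(9.37e-10, 1e-10, 2.53e-47, 1e-12, 0.01))
  kept <- filter_de(de, selection_config())
  # 0.87 passes (linear 1.83 > 1.5); 0.50 fails (1.41); -1.93 passes on
  # absolute value; p = 0.01 fails the 0.001 cut
  expect_setequal(kept$gene, c("AQP4-AS1", "MEG3"))
})

test_that("SNP-in-interval pairing is half-open and brute-force exact", {
  ivs <- list(lnc_interval("chr1", 100, 200, "A"),
              lnc_interval("chr1", 150, 250, "B"),   # overlaps A
              lnc_interval("chr2", 0, 50, "C"))
  rec <- function(id, chrom, pos1) gwas_record(id, chrom, pos1,
                                               reported_or = 1.1, maf = 0.3)
  recs <- list(rec("rs_at_start", "chr1", 101),   # 0-based 100: inside A
               rec("rs_at_end", "chr1", 200),     # 0-based 199: A and B
               rec("rs_past_end", "chr1", 201),   # 0-based 200: B only
               rec("rs_beyond", "chr1", 251),     # 0-based 250: outside
               rec("rs_chr2", "chr2", 1))         # 0-based 0: inside C
  pairs <- intersect_snps_lncrnas(recs, ivs)
  # independent brute-force scan over every SNP x interval combination
  brute <- 0L
  for (r in recs) for (v in ivs)
    if (r$chrom == v$chrom && (r$pos - 1) >= v$start && (r$pos - 1) < v$end)
      brute <- brute + 1L
  expect_equal(nrow(pairs), brute)
  expect_equal(sum(pairs$snp_id == "rs_at_end"), 2L)  # two overlapping hosts
  expect_false("rs_beyond" %in% pairs$snp_id)
  # build mismatch errors
  recs_b38 <- list(gwas_record("rs1", "chr1", 150, reported_or = 1.1,
                               maf = 0.3, build = "GRCh38"))
  ivs_b37 <- list(lnc_interval("chr1", 100, 200, "A", build = "GRCh37"))
  expect_error(intersect_snps_lncrnas(recs_b38, ivs_b37), "build mismatch")
})

test_that("MAF filter is strictly greater-than", {
  pairs <- data.frame(snp_id = c("a", "b", "c"),
                      maf = c(0.27, 0.20, 0.46))
  kept <- filter_maf(pairs, selection_config())
  expect_setequal(kept$snp_id, c("a", "c"))  # 0.20 exactly is excluded
})

test_that("subtype filter keeps any non-ns flag and drops all-ns rows", {
  cand <- data.frame(
    snp_id = c("x", "y", "z"),
    subtype_flags = c("ER+=down,HER2+=up", "ns", ""))
  kept <- filter_subtype_de(cand)
  expect_equal(kept$snp_id, "x")
})

test_that("rank_select walks rows by OR collecting distinct SNPs", {
  cand <- cohort_candidate_table()
  sel <- rank_select(cand, selection_config(n_select = 4))
  # top ORs 1.24, 1.23 (a two-SNP row), 1.17 -> exactly the genotyped four
  expect_setequal(as.character(sel),
                  c("rs7716600", "rs4784227", "rs3803662", "rs4415084"))
  # a single candidate with n_select = 4 warns and returns it
  expect_warning(one <- rank_select(cand[1, ], selection_config(n_select = 4)),
                 "available")
  expect_equal(as.character(one), "rs2594714")
  # equal ORs: rsID lexicographic order decides, and the tie is flagged
  tied <- data.frame(snp_id = c("rsB", "rsA"), reported_or = c(1.2, 1.2))
  expect_message(s <- rank_select(tied, selection_config(n_select = 1)),
                 "tie")
  expect_equal(as.character(s), "rsA")
  expect_true(attr(s, "tie_break"))
})

test_that("filters commute and are idempotent (set-intersection semantics)", {
  set.seed(77)
  cand <- data.frame(
    snp_id = sprintf("rs%03d", 1:40),
    gene = sprintf("LNC%02d", 1:40),
    log2fc = rnorm(40, sd = 1.5),
    p_value = 10^runif(40, -12, -1),
    maf = runif(40, 0.05, 0.5),
    subtype_flags = sample(c("ER+=up", "ns", ""), 40, replace = TRUE),
    stringsAsFactors = FALSE)
  cfg <- selection_config()
  ab <- filter_maf(filter_de(cand, cfg), cfg)
  ba <- filter_de(filter_maf(cand, cfg), cfg)
  expect_setequal(ab$snp_id, ba$snp_id)
  abc <- filter_subtype_de(ab)
  cab <- filter_maf(filter_de(filter_subtype_de(cand), cfg), cfg)
  expect_setequal(abc$snp_id, cab$snp_id)
  # idempotence
  expect_identical(filter_de(ab, cfg), ab)
  expect_identical(filter_maf(ab, cfg), ab)
  expect_identical(filter_subtype_de(abc), abc)
})

test_that("a fixture with 23 candidates and 14 flagged yields 14 survivors", {
  # engineered to the published cardinality: 23 pass DE+MAF, 14 carry a
  # non-ns subtype flag, and the four top-OR SNPs are the genotyped ones
  flagged <- cohort_candidate_table()          # 14 rows, all flagged
  extra <- data.frame(
    lncrna = sprintf("EXTRA%02d", 1:9),
    log2fc = rep(c(2.5, -2.5, 3), each = 3),
    p_value = rep(1e-20, 9),
    subtype_flags = "ns",
    snp_id = sprintf("rs99%03d", 1:9),
    reported_or = seq(1.01, 1.09, by = 0.01),
    maf = rep(0.3, 9), stringsAsFactors = FALSE)
  cand23 <- rbind(flagged, extra)
  expect_equal(nrow(cand23), 23L)
  surv <- filter_subtype_de(filter_maf(filter_de(cand23), selection_config()))
  expect_equal(nrow(surv), 14L)
  sel <- rank_select(surv, selection_config(n_select = 4))
  expect_setequal(as.character(sel),
                  c("rs7716600", "rs4784227", "rs3803662", "rs4415084"))
})

test_that("the full pipeline recovers planted candidates end to end", {
  # three lncRNAs: one passes everything, one fails DE, one fails MAF
  ivs <- list(lnc_interval("chr1", 1000, 2000, "LNC_HIT"),
              lnc_interval("chr1", 3000, 4000, "LNC_FLAT"),
              lnc_interval("chr1", 5000, 6000, "LNC_RARE"))
  spec <- expression_spec(
    n_genes = 3, group_sizes = c(tumor = 60, normal = 60),
    log2fc = c(1.92, 0, 2.5), noise_sd = 0.4, seed = 99)
  x <- gen_expression(spec)
  rownames(x$values) <- c("LNC_HIT", "LNC_FLAT", "LNC_RARE")
  de <- compute_de(x, "tumor", "normal")
  de$subtype_flags <- c("ER+=up", "ER+=up", "ER+=up")
  recs <- list(
    gwas_record("rs_hit", "chr1", 1500, reported_or = 1.3, maf = 0.3),
    gwas_record("rs_flat", "chr1", 3500, reported_or = 1.2, maf = 0.3),
    gwas_record("rs_rare", "chr1", 5500, reported_or = 1.4, maf = 0.15))
  out <- select_candidates(de, recs, ivs, selection_config(n_select = 1))
  expect_equal(nrow(out$candidates), 3L)
  expect_equal(out$surviving$snp_id, "rs_hit")
  expect_equal(as.character(out$selected), "rs_hit")
  trail <- out$candidates[out$candidates$snp_id == "rs_rare", ]
  expect_true(trail$pass_de)
  expect_false(trail$pass_maf)
})
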