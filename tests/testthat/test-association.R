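test_that("genotype counting is complete-case and pooled-minor oriented", {
  d <- toy_dataset()
  cc <- count_genotypes(d, "rs0001", c("case", "control"))
  # S8 (control) is missing at rs0001 -> control total 3
  expect_equal(unname(rowSums(cc$counts)), c(4, 3))
  # case: CC, CT, TC, TT -> (1, 2, 1); control: CC, CC, CT -> (2, 1, 0)
  expect_equal(unname(cc$counts["case", ]), c(1, 2, 1))
  expect_equal(unname(cc$counts["control", ]), c(2, 1, 0))
  # pooled T frequency = (2*1 + 3)/14 < 0.5, so minor stays T
  expect_identical(cc$snp$minor_allele, "T")
})

test_that("minor allele flips to the pooled-rarer allele unless overridden", {
  snp <- toy_snp("rs0009", "C", "T")   # declared minor T
  samples <- data.frame(sample_id = paste0("S", 1:6),
                        group = rep(c("case", "control"), each = 3))
  g <- cbind(rs0009 = c("TT", "TT", "CT", "TT", "CT", "TT"))
  rownames(g) <- samples$sample_id
  d <- genotype_dataset(samples, g, list(snp))
  cc <- count_genotypes(d, "rs0009", c("case", "control"))
  expect_identical(cc$snp$minor_allele, "C")   # C is rarer here
  cc2 <- count_genotypes(d, "rs0009", c("case", "control"),
                         minor_from = "snp_def")
  expect_identical(cc2$snp$minor_allele, "T")
  # counts are consistent either way (hom_minor column swaps)
  expect_equal(unname(cc$counts[, "hom_major"]),
               unname(cc2$counts[, "hom_minor"]))
})

test_that("count_genotypes errors when a group is fully missing", {
  d <- toy_dataset()
  d$genotypes[d$samples$group == "control", "rs0001"] <- NA
  expect_error(count_genotypes(d, "rs0001", c("case", "control")),
               "zero non-missing")
  expect_error(count_genotypes(d, "rs9999"), "not in dataset")
})

test_that("allele frequencies match the hand formula per group and pooled", {
  cc <- toy_counts(case = c(25, 50, 25), control = c(10, 20, 10))
  af <- allele_frequency(cc, "minor")
  expect_equal(af$freq, c(0.5, 0.5, 0.5))
  afM <- allele_frequency(cc, "major")
  expect_equal(afM$freq, 1 - af$freq)
  # explicit base same as role name
  expect_equal(allele_frequency(cc, "T")$freq, af$freq)
  expect_error(allele_frequency(cc, "G"), "not an allele")
})

test_that("HWE chi-square matches the expected-count oracle", {
  # exact HWE proportions -> chi2 = 0, p = 1
  r <- hwe_test(toy_counts(case = c(25, 50, 25)), "case")
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  expect_equal(sum(r$expected), 100)
  # all hets: classic maximal-disequilibrium case
  r2 <- hwe_test(toy_counts(case = c(0, 100, 0)), "case")
  expect_equal(r2$chi2, 100)
  # random tables vs oracle
  set.seed(421)
  for (i in 1:20) {
    cc <- c(sample(0:50, 2), sample(1:50, 1))
    r3 <- hwe_test(toy_counts(case = cc), "case")
    o <- oracle_hwe(cc)
    expect_equal(r3$chi2, o$chi2)
    expect_equal(r3$p_value, o$p)
    expect_equal(sum(r3$expected), sum(cc))
  }
})

test_that("HWE chi-square is invariant under allele relabeling", {
  set.seed(99)
  for (i in 1:10) {
    cc <- sample(1:80, 3)
    a <- hwe_test(toy_counts(case = cc), "case")
    b <- hwe_test(toy_counts(case = rev(cc)), "case")
    expect_equal(a$chi2, b$chi2)
  }
})

test_that("monomorphic SNP gives a degenerate but defined HWE result", {
  r <- hwe_test(toy_counts(case = c(40, 0, 0)), "case")
  expect_true(r$degenerate)
  expect_equal(r$chi2, 0)
})

test_that("model tables collapse counts per inheritance model", {
  cc <- toy_counts(case = c(104, 132, 49), control = c(100, 182, 75))
  cells <- function(m) matrix(as.numeric(m), nrow(m))
  dom <- build_model_table(cc, "dominant")
  expect_equal(cells(dom), rbind(c(104, 100), c(181, 257)))
  rec <- build_model_table(cc, "recessive")
  expect_equal(cells(rec), rbind(c(236, 282), c(49, 75)))
  ovr <- build_model_table(cc, "overdominant")
  expect_equal(cells(ovr), rbind(c(153, 175), c(132, 182)))
  cod <- build_model_table(cc, "codominant")
  expect_equal(nrow(cod), 3L)
  # conservation: every model table sums to the genotype total
  for (m in c("codominant", "dominant", "recessive", "overdominant"))
    expect_equal(sum(build_model_table(cc, m)), sum(cc$counts))
})

test_that("odds ratio matches the cross-product oracle in both orientations", {
  set.seed(7)
  for (i in 1:25) {
    cells <- sample(1:200, 4)
    tab <- rbind(cells[1:2], cells[3:4])
    o2 <- odds_ratio(tab, outcome = "col2")
    o1 <- odds_ratio(tab, outcome = "col1")
    expect_equal(o2$or_value,
                 oracle_or_col2(cells[1], cells[2], cells[3], cells[4]))
    # reciprocal symmetry between orientations
    expect_equal(o2$or_value * o1$or_value, 1)
    # Wald CI contains the point estimate
    expect_lte(o2$ci_lo, o2$or_value)
    expect_gte(o2$ci_hi, o2$or_value)
  }
})

test_that("group-column swap inverts every OR", {
  cc <- toy_counts(case = c(40, 40, 20), control = c(30, 50, 20))
  swapped <- genotype_counts(cc$snp, cc$counts[c(2, 1), ])
  a <- run_models(cc)$results
  b <- run_models(swapped)$results
  expect_equal(a$or * b$or, rep(1, nrow(a)))
})

test_that("Wald CI width shrinks as all cells scale up", {
  tab <- rbind(c(20, 30), c(35, 15))
  widths <- sapply(c(1, 2, 5, 10), function(k) {
    o <- odds_ratio(tab * k)
    log(o$ci_hi) - log(o$ci_lo)
  })
  expect_true(all(diff(widths) < 0))
  # point estimate unchanged by scaling
  expect_equal(odds_ratio(tab * 10)$or_value, odds_ratio(tab)$or_value)
})

test_that("zero cells trigger Haldane-Anscombe; empty margins are undefined", {
  o <- odds_ratio(rbind(c(10, 20), c(0, 5)))
  expect_true(o$haldane)
  expect_equal(o$or_value, (5.5 * 10.5) / (0.5 * 20.5))
  u <- odds_ratio(rbind(c(0, 0), c(5, 5)))
  expect_true(u$undefined)
  expect_true(is.na(u$or_value))
})

test_that("G test matches oracle, co-reports Pearson, handles zero cells", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(sample(1:80, 4), 2)
    lr <- lr_test(m)
    o <- oracle_g_test(m)
    expect_equal(lr$g_stat, o$g)
    expect_equal(lr$p_value, o$p)
    # Pearson cross-checked against stats::chisq.test (no correction)
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(lr$pearson_stat, unname(ct$statistic))
  }
  # independence-perfect table: G = 0, p = 1
  perf <- lr_test(rbind(c(10, 20), c(30, 60)))
  expect_equal(perf$g_stat, 0)
  expect_equal(perf$p_value, 1)
  # zero observed cell contributes 0 and is flagged
  z <- lr_test(rbind(c(0, 10), c(20, 30)))
  expect_equal(z$zero_cells, 1)
  expect_true(is.finite(z$g_stat))
  expect_error(lr_test(rbind(c(0, 0), c(5, 5))), "degenerate")
})

test_that("G and Pearson agree as the relative deviation from independence shrinks", {
  # fixed absolute perturbation around growing independence tables: the
  # statistics stay O(1) while their disagreement vanishes
  base <- outer(c(0.4, 0.6), c(0.55, 0.45))
  pert <- rbind(c(5, -5), c(-5, 5))
  gap <- sapply(c(100, 1000, 10000), function(n) {
    lr <- lr_test(base * n + pert)
    abs(lr$g_stat - lr$pearson_stat)
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 1e-3)
})

test_that("run_models produces one block per model with shared block p", {
  cc <- toy_counts(case = c(50, 60, 30), control = c(55, 65, 20))
  m <- run_models(cc)
  expect_s3_class(m, "model_results")
  expect_equal(unique(m$results$model),
               c("codominant", "dominant", "recessive", "overdominant"))
  expect_equal(nrow(m$results), 5L)  # 2 codominant rows + 3 model rows
  expect_equal(m$n_tests, 4L)
  # codominant rows share the 2-df block p
  cod <- m$results[m$results$model == "codominant", ]
  expect_equal(cod$p_lr[1], cod$p_lr[2])
  expect_named(m$hwe, c("case", "control"))
  # dataset method agrees with counts method
  d <- dataset_from_counts(cc)
  m2 <- run_models(d, "rs0001", group_pair = c("case", "control"))
  expect_equal(m2$results$or, m$results$or)
})

test_that("synthetic cohorts recover the analytic genotype-model OR", {
  # per-group genotype probabilities make the dominant OR analytic
  probs_case <- c(104, 132, 49) / 285
  probs_ctrl <- c(100, 182, 75) / 357
  analytic <- oracle_or_col2(probs_case[1], probs_ctrl[1],
                             sum(probs_case[2:3]), sum(probs_ctrl[2:3]))
  spec <- cohort_spec(
    c(case = 1e5, control = 1e5),
    list(rs0001 = list(snp = toy_snp(),
                       probs = rbind(case = probs_case,
                                     control = probs_ctrl))),
    seed = 2024)
  d <- gen_cohort(spec)
  m <- run_models(d, "rs0001", group_pair = c("case", "control"))
  est <- m$results$or[m$results$model == "dominant"]
  # 2 SEs of the log OR at n = 1e5 per group
  se <- sqrt(sum(1 / (1e5 * c(probs_case[1], probs_ctrl[1],
                              sum(probs_case[2:3]), sum(probs_ctrl[2:3])))))
  expect_lt(abs(log(est) - log(analytic)), 2 * se)
})
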