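#' SNP definitions of the four genotyped lncRNA-SNPs
#'
#' The four breast-cancer-associated SNPs genotyped in the bundled Brazilian
#' case-control cohort, with their host lncRNAs: rs3803662 and rs4784227 in
#' CASC16 (chr16), rs4415084 in LINC02224 (chr5) and rs7716600 in AC093297.2
#' (chr5).  Positions are GRCh37.  Major/minor assignment follows the cohort
#' itself.
#'
#' @return Named list of [snp_def()]s.
#' @export
cohort_snp_defs <- function() {
  defs <- list(
    snp_def("rs3803662", "chr16", 52586341, "G", "A",
            host_gene = "CASC16", build = "GRCh37"),
    snp_def("rs4415084", "chr5", 44662515, "C", "T",
            host_gene = "LINC02224", build = "GRCh37"),
    snp_def("rs4784227", "chr16", 52599188, "C", "T",
            host_gene = "CASC16", build = "GRCh37"),
    snp_def("rs7716600", "chr5", 44649944, "C", "A",
            host_gene = "AC093297.2", build = "GRCh37"))
  setNames(defs, vapply(defs, `[[`, "", "snp_id"))
}

#' Case-control genotype counts of the Brazilian cohort
#'
#' Genotype counts of the four lncRNA-SNPs in a published Brazilian
#' breast-cancer case-control study (291 patients enrolled, 370 controls;
#' per-SNP totals are smaller because genotyping is complete-case per SNP).
#' These are the golden tables the association engine reproduces exactly.
#'
#' @return Named list (by rsID) of [genotype_counts()] with groups
#'   `case`/`control`.
#' @examples
#' run_models(cohort_genotype_counts()[["rs7716600"]])
#' @export
cohort_genotype_counts <- function() {
  defs <- cohort_snp_defs()
  make <- function(id, case, control)
    genotype_counts(defs[[id]], rbind(case = case, control = control))
  list(
    rs3803662 = make("rs3803662", c(125, 121, 27), c(172, 151, 44)),
    rs4415084 = make("rs4415084", c(104, 132, 49), c(100, 182, 75)),
    rs4784227 = make("rs4784227", c(153, 94, 23), c(199, 130, 26)),
    rs7716600 = make("rs7716600", c(153, 94, 7), c(196, 118, 24)))
}

#' Clinically stratified genotype counts of the cohort's cases
#'
#' Case-only genotype counts stratified by the two clinical parameters with
#' published significant associations: rs4415084 by progesterone-receptor
#' status (negative n = 62, positive n = 166) and rs7716600 by lymph-node
#' status (negative n = 125, positive n = 90).  Column 1 is the negative
#' stratum, so the default OR orientation reproduces the published values.
#'
#' @return Named list of [genotype_counts()].
#' @export
cohort_strata_counts <- function() {
  defs <- cohort_snp_defs()
  list(
    rs4415084_pr = genotype_counts(
      defs[["rs4415084"]],
      rbind(negative = c(19, 36, 7), positive = c(56, 72, 38))),
    rs7716600_lymph = genotype_counts(
      defs[["rs7716600"]],
      rbind(negative = c(68, 53, 4), positive = c(61, 27, 2))))
}

#' Candidate lncRNA-SNP table from the source selection run
#'
#' The 14 lncRNA-SNP candidates that passed all three selection filters in
#' the published analysis: host lncRNA, tumor-vs-normal log2 fold change and
#' DE p-value, subtype DE flags, rsID(s) (slash-separated when one lncRNA
#' carries two SNPs), GWAS odds ratio and minor allele frequency.  Used as a
#' ranking fixture: [rank_select()] on this table with `n_select = 4`
#' returns the four genotyped SNPs.
#'
#' @return `data.frame` with columns `lncrna`, `log2fc`, `p_value`,
#'   `subtype_flags`, `snp_id`, `reported_or`, `maf`.
#' @export
cohort_candidate_table <- function() {
  data.frame(
    lncrna = c("AC020916.1", "AC093297.2", "AL358075.2", "AQP4-AS1",
               "CASC16", "CRYZL2P-SEC16B-201", "LINC-PINT", "LINC02224",
               "LINC01977", "LINC00511", "LINC00536", "LINC00578", "MEG3",
               "MIR4435-2HG"),
    log2fc = c(1.99, 1.86, 1.45, 0.87, 1.92, -0.80, -0.69, 3.92, 1.48,
               1.72, 1.05, 1.91, -1.93, 0.88),
    p_value = c(1.27e-147, 2.70e-15, 3.39e-11, 9.37e-10, 9.57e-15,
                1.90e-12, 1.14e-6, 3.14e-100, 5.16e-19, 2.70e-14, 1.43e-5,
                2.70e-16, 2.53e-47, 6.77e-10),
    subtype_flags = c("ER+=down", "ER+=down,HER2+=up", "HER2+=down",
                      "ER+=up", "ER+=up", "HER2+=up", "HER2-=up",
                      "ER+=down,HER2+=up", "ER+=down", "ER+=up", "ER+=up",
                      "ER+=down,HER2+=down", "ER+=up", "HER2+=down"),
    snp_id = c("rs2594714", "rs7716600", "rs1707302", "rs527616",
               "rs4784227/rs3803662", "rs575908", "rs68056147",
               "rs4415084", "rs745570", "rs11652463", "rs13267382",
               "rs7430456", "rs2295389", "rs200484318"),
    reported_or = c(1.04, 1.24, 1.04, 1.03, 1.23, 1.03, 1.05, 1.17, 1.03,
                    1.04, 1.03, 1.02, 1.03, 1.04),
    maf = c(0.42, 0.27, 0.37, 0.23, 0.25, 0.35, 0.24, 0.46, 0.38, 0.43,
            0.34, 0.44, 0.27, 0.36),
    stringsAsFactors = FALSE)
}

#' Published two-locus haplotype frequencies for rs3803662/rs4784227
#'
#' Pooled haplotype frequencies of the rs3803662/rs4784227 pair (alleles in
#' that locus order) estimated in the cohort: GC 0.67, AT 0.25, AC 0.0735,
#' GT 0.0081.  The printed column sums to 1.0016; `normalize = TRUE`
#' (default) rescales by the sum so the vector is a valid frequency
#' distribution for simulation.
#'
#' @param normalize Rescale to sum exactly 1.
#' @return Named numeric vector in (A1B1, A1B2, A2B1, A2B2) order, i.e.
#'   `c(GC, GT, AC, AT)`.
#' @export
cohort_haplotype_frequencies <- function(normalize = TRUE) {
  f <- c(GC = 0.67, GT = 0.0081, AC = 0.0735, AT = 0.25)
  if (normalize) f <- f / sum(f)
  f
}

#' Generating spec emulating the Brazilian cohort
#'
#' A ready-made [cohort_spec()] whose defaults are the study conditions of
#' the bundled cohort: 291 cases and 370 controls, per-group genotype
#' probabilities equal to the cohort's empirical genotype fractions, and
#' per-SNP per-group missingness backed out of the published per-SNP totals
#' (e.g. rs7716600 was called in 254 of 291 cases).
#'
#' @param n_per_group Group sizes; defaults to the enrolled cohort.
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @examples
#' d <- gen_cohort(default_cohort_spec(seed = 42))
#' @export
default_cohort_spec <- function(n_per_group = c(case = 291, control = 370),
                                seed = 1L) {
  counts <- cohort_genotype_counts()
  enrolled <- c(case = 291, control = 370)
  snp_specs <- lapply(counts, function(cc) {
    probs <- sweep(cc$counts, 1, rowSums(cc$counts), "/")
    miss <- 1 - rowSums(cc$counts) / enrolled[rownames(cc$counts)]
    miss <- pmax(miss, 0)
    names(miss) <- rownames(cc$counts)
    list(snp = cc$snp, probs = probs, missing = miss)
  })
  cohort_spec(n_per_group, snp_specs, seed = seed)
}
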