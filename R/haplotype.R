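#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood estimation of the four haplotype frequencies for a pair
#' of biallelic SNPs from unphased genotypes.  Only double heterozygotes are
#' phase-ambiguous; the E-step splits them between the two phase resolutions
#' (cis: A1B1/A2B2, trans: A1B2/A2B1) in proportion to the current haplotype
#' frequency products, and the M-step renormalizes expected haplotype counts.
#' Frequencies are initialized at linkage-equilibrium products of the
#' observed allele frequencies, which makes the (symmetric) double-het-only
#' case deterministic.  Iteration stops when the largest absolute frequency
#' change falls below `tol` (default 1e-8) or after `max_iter` iterations;
#' non-convergence is flagged, not raised.  Samples missing either genotype
#' are excluded.
#'
#' @param dataset A [genotype_dataset()] containing both SNPs.
#' @param snp_a,snp_b rsIDs of the two loci.
#' @param group Group label to restrict to, or `NULL` (default) for all
#'   samples pooled.
#' @param tol,max_iter Convergence tolerance on frequencies and iteration cap.
#' @return Object of class `haplotype_estimate`: `haplotypes` (labels
#'   "A1B1", "A1B2", "A2B1", "A2B2" named by their allele strings, e.g.
#'   `"GC"`), `freqs` (4 frequencies summing to 1), `loglik_trace`
#'   (non-decreasing), `n_iter`, `converged`, `n_samples`, `phase_symmetric`.
#' @seealso [ld_from_haplotypes()], [haplotype_association()]
#' @export
em_haplotypes <- function(dataset, snp_a, snp_b, group = NULL,
                          tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  for (s in c(snp_a, snp_b))
    if (!s %in% names(dataset$snp_defs)) stop("SNP ", s, " not in dataset")
  keep <- rep(TRUE, nrow(dataset$samples))
  if (!is.null(group)) keep <- dataset$samples$group %in% group
  ga <- dataset$genotypes[keep, snp_a]
  gb <- dataset$genotypes[keep, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  if (n == 0L) stop("zero usable samples (all missing at one locus)")
  da <- dataset$snp_defs[[snp_a]]; db <- dataset$snp_defs[[snp_b]]
  # copies of the A2/B2 (minor) allele per sample: 0, 1, 2
  dose <- function(g, d) {
    (substr(g, 1, 1) == d$minor_allele) + (substr(g, 2, 2) == d$minor_allele)
  }
  xa <- dose(ga, da); xb <- dose(gb, db)
  hap_names <- c(paste0(da$major_allele, db$major_allele),
                 paste0(da$major_allele, db$minor_allele),
                 paste0(da$minor_allele, db$major_allele),
                 paste0(da$minor_allele, db$minor_allele))
  # genotype class counts over (xa, xb) in {0,1,2}^2
  cls <- table(factor(xa, 0:2), factor(xb, 0:2))
  n_dh <- cls["1", "1"]           # double heterozygotes: phase-ambiguous
  # fixed haplotype counts contributed by the 8 unambiguous classes;
  # order: f11, f12, f21, f22 for haplotypes A1B1, A1B2, A2B1, A2B2
  fixed <- c(
    2 * cls["0", "0"] + cls["0", "1"] + cls["1", "0"],
    2 * cls["0", "2"] + cls["0", "1"] + cls["1", "2"],
    2 * cls["2", "0"] + cls["1", "0"] + cls["2", "1"],
    2 * cls["2", "2"] + cls["2", "1"] + cls["1", "2"])
  pa1 <- 1 - mean(xa) / 2; pb1 <- 1 - mean(xb) / 2
  f <- c(pa1 * pb1, pa1 * (1 - pb1), (1 - pa1) * pb1, (1 - pa1) * (1 - pb1))
  loglik <- function(f) {
    # log-likelihood over haplotype pairs; unambiguous classes contribute
    # their fixed haplotype counts, double hets the two-phase mixture.
    # Constant multiplicity factors (2 per heterozygous pair) are omitted.
    p_dh <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
    sum(fixed * log(pmax(f, .Machine$double.xmin))) +
      if (n_dh > 0) n_dh * log(max(p_dh, .Machine$double.xmin)) else 0
  }
  trace <- loglik(f)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step: split double hets between cis (A1B1+A2B2) and trans
    cis <- f[1] * f[4]; trans <- f[2] * f[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    trace <- c(trace, loglik(f))
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(
    haplotypes = setNames(hap_names, c("A1B1", "A1B2", "A2B1", "A2B2")),
    freqs = setNames(f, hap_names),
    loglik_trace = trace, n_iter = it, converged = converged,
    n_samples = n, snp_a = da, snp_b = db, group = group,
    phase_symmetric = n_dh == n),
    class = "haplotype_estimate")
}

#' @export
print.haplotype_estimate <- function(x, ...) {
  cat(sprintf("<haplotype_estimate> %s/%s, n = %d, %s in %d iterations\n",
              x$snp_a$snp_id, x$snp_b$snp_id, x$n_samples,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(round(x$freqs, 4))
  invisible(x)
}

#' Linkage disequilibrium statistics from haplotype frequencies
#'
#' Given the four haplotype frequencies (f11, f12, f21, f22) for loci A and B:
#' `D = f11 - pA1 * pB1`; `D' = D / Dmax` where for `D > 0`
#' `Dmax = min(pA1 * qB2, qA2 * pB1)` (the mirror-image minimum for `D < 0`);
#' `r2 = D^2 / (pA1 * qA2 * pB1 * qB2)`.  Here `pA1 = f11 + f12` is the
#' frequency of allele A1 and `qA2 = 1 - pA1`, similarly for locus B.
#'
#' @param freqs Numeric vector of 4 haplotype frequencies in the order
#'   (A1B1, A1B2, A2B1, A2B2), summing to 1, or a [em_haplotypes()] result.
#' @return List of class `ld_stats`: `d`, `d_prime`, `r2`, and the marginal
#'   allele frequencies `p_a1`, `p_b1`.
#' @examples
#' ld_from_haplotypes(c(0.5, 0, 0, 0.5))   # complete LD: D' = 1, r2 = 1
#' @export
ld_from_haplotypes <- function(freqs) {
  if (inherits(freqs, "haplotype_estimate")) freqs <- freqs$freqs
  freqs <- unname(freqs)
  stopifnot(length(freqs) == 4L, all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  pa <- freqs[1] + freqs[2]; pb <- freqs[1] + freqs[3]
  qa <- 1 - pa; qb <- 1 - pb
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("monomorphic locus: LD undefined")
  d <- freqs[1] - pa * pb
  dmax <- if (d >= 0) min(pa * qb, qa * pb) else min(pa * pb, qa * qb)
  d_prime <- if (dmax == 0) 0 else d / dmax
  r2 <- d^2 / (pa * qa * pb * qb)
  structure(list(d = d, d_prime = d_prime, r2 = r2, p_a1 = pa, p_b1 = pb),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD: D = %.4g, D' = %.3f, r2 = %.3f\n", x$d, x$d_prime, x$r2))
  invisible(x)
}

#' Haplotype-level case-control association
#'
#' Converts per-group EM haplotype frequencies into estimated haplotype
#' counts (`2 * N * freq`, rounded to the nearest integer and flagged as
#' estimated) and tests each haplotype against the reference (most frequent
#' pooled) haplotype in a 2x2 table via [odds_ratio()] and [lr_test()].  The
#' reference haplotype's OR is 1 by construction.
#'
#' @param est_1,est_2 [em_haplotypes()] results for the column-1 and column-2
#'   groups (e.g. cases and controls).
#' @param outcome OR orientation, see [odds_ratio()].
#' @return `data.frame` of class `haplotype_association`: one row per
#'   haplotype with `haplotype`, `allele_a`, `allele_b`, `freq_pooled`,
#'   `freq_1`, `freq_2`, `count_1`, `count_2`, `or`, `ci_lo`, `ci_hi`, `p_lr`,
#'   reference row first.
#' @export
haplotype_association <- function(est_1, est_2, outcome = c("col2", "col1")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(est_1, "haplotype_estimate"),
            inherits(est_2, "haplotype_estimate"))
  if (!est_1$converged || !est_2$converged)
    warning("using non-converged haplotype estimates")
  if (!identical(unname(est_1$haplotypes), unname(est_2$haplotypes)))
    stop("haplotype labels differ between groups")
  haps <- est_1$haplotypes
  n1 <- 2 * est_1$n_samples; n2 <- 2 * est_2$n_samples
  c1 <- round(n1 * est_1$freqs); c2 <- round(n2 * est_2$freqs)
  pooled <- (n1 * est_1$freqs + n2 * est_2$freqs) / (n1 + n2)
  ref <- which.max(pooled)
  if (c1[ref] == 0 || c2[ref] == 0)
    stop("reference haplotype has zero estimated count in a group")
  ord <- c(ref, setdiff(order(pooled, decreasing = TRUE), ref))
  rows <- lapply(ord, function(i) {
    if (i == ref) {
      or <- 1; lo <- NA_real_; hi <- NA_real_; p <- NA_real_
    } else {
      tab <- rbind(c(c1[ref], c2[ref]), c(c1[i], c2[i]))
      o <- odds_ratio(tab, outcome = outcome)
      p <- tryCatch(lr_test(tab)$p_value, error = function(e) NA_real_)
      or <- o$or_value; lo <- o$ci_lo; hi <- o$ci_hi
    }
    data.frame(haplotype = haps[[i]],
               allele_a = substr(haps[[i]], 1, 1),
               allele_b = substr(haps[[i]], 2, 2),
               freq_pooled = unname(pooled[i]),
               freq_1 = unname(est_1$freqs[i]), freq_2 = unname(est_2$freqs[i]),
               count_1 = unname(c1[i]), count_2 = unname(c2[i]),
               or = or, ci_lo = lo, ci_hi = hi, p_lr = p,
               is_reference = i == ref, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("haplotype_association", "data.frame")
  out
}
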