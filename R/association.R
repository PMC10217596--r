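#' Genotype counts for one SNP in two groups
#'
#' The atom behind every association table: per-group counts of
#' (hom-major, het, hom-minor) genotypes for a single SNP.
#'
#' @param snp A [snp_def()].
#' @param counts Integer matrix 2 x 3, rows = the two groups in declared
#'   column order, columns = `hom_major`, `het`, `hom_minor`.
#' @return Object of class `genotype_counts`.
#' @examples
#' snp <- snp_def("rs4415084", "chr5", 44662515, "C", "T")
#' genotype_counts(snp, rbind(case = c(104, 132, 49), control = c(100, 182, 75)))
#' @export
genotype_counts <- function(snp, counts) {
  stopifnot(inherits(snp, "snp_def"))
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || ncol(counts) != 3L)
    stop("counts must be a 2 x 3 matrix (two groups x three genotype classes)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (is.null(rownames(counts))) stop("counts rows must be named by group")
  colnames(counts) <- c("hom_major", "het", "hom_minor")
  structure(list(snp = snp, counts = counts,
                 groups = rownames(counts)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cls <- genotype_classes(x$snp)
  m <- x$counts; colnames(m) <- cls
  cat(sprintf("<genotype_counts> %s (n = %s)\n", x$snp$snp_id,
              paste(rowSums(m), collapse = " / ")))
  print(m)
  invisible(x)
}

#' Count genotypes for one SNP in two groups
#'
#' Complete-case per SNP: samples with a missing genotype at this SNP are
#' excluded, so per-SNP totals may be smaller than group enrolment.  By
#' default the minor allele is the rarer allele in the pooled (both-group)
#' sample; set `minor_from = "snp_def"` to keep the `snp_def` assignment even
#' if it is the commoner allele in this cohort.
#'
#' @param dataset A [genotype_dataset()].
#' @param snp_id rsID present in the dataset.
#' @param group_pair Character vector of two group labels; the first is the
#'   column-1 group of the resulting tables.
#' @param minor_from `"pooled"` (default) or `"snp_def"`.
#' @return A [genotype_counts()] object.
#' @export
count_genotypes <- function(dataset, snp_id,
                            group_pair = unique(dataset$samples$group),
                            minor_from = c("pooled", "snp_def")) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  minor_from <- match.arg(minor_from)
  if (!snp_id %in% names(dataset$snp_defs))
    stop("SNP ", snp_id, " not in dataset")
  stopifnot(length(group_pair) == 2L)
  if (!all(group_pair %in% dataset$samples$group))
    stop("group(s) not present: ",
         paste(setdiff(group_pair, dataset$samples$group), collapse = ", "))
  snp <- dataset$snp_defs[[snp_id]]
  cls <- genotype_classes(snp)
  m <- matrix(0L, 2, 3, dimnames = list(group_pair, names(cls)))
  for (g in group_pair) {
    gt <- dataset$genotypes[dataset$samples$group == g, snp_id]
    gt <- gt[!is.na(gt)]
    if (length(gt) == 0L)
      stop("group '", g, "' has zero non-missing samples for ", snp_id)
    m[g, ] <- as.integer(table(factor(gt, levels = cls)))
  }
  if (minor_from == "pooled") {
    maf <- (2 * sum(m[, "hom_minor"]) + sum(m[, "het"])) / (2 * sum(m))
    if (maf > 0.5) {  # swap allele roles so "minor" is rarer in this cohort
      snp <- snp_def(snp$snp_id, snp$chrom, snp$pos,
                     major_allele = snp$minor_allele,
                     minor_allele = snp$major_allele,
                     host_gene = snp$host_gene, build = snp$build)
      m <- m[, c(3, 2, 1)]
      colnames(m) <- names(cls)
    }
  }
  genotype_counts(snp, m)
}

#' Allele frequencies from genotype counts
#'
#' Frequency of the chosen allele per group and pooled over both groups:
#' `freq = (2 * n_hom_allele + n_het) / (2 * n_total)`.
#'
#' @param counts A [genotype_counts()].
#' @param allele `"minor"`, `"major"`, or an explicit base.
#' @return `data.frame` with columns `group` (the two groups plus
#'   `"pooled"`), `allele`, `freq`.
#' @examples
#' cc <- cohort_genotype_counts()[["rs4784227"]]
#' allele_frequency(cc, allele = "T")   # pooled row rounds to 0.26
#' @export
allele_frequency <- function(counts, allele = "minor") {
  stopifnot(inherits(counts, "genotype_counts"))
  snp <- counts$snp
  base <- switch(allele, minor = snp$minor_allele, major = snp$major_allele,
                 toupper(allele))
  if (base == snp$minor_allele) hom <- "hom_minor"
  else if (base == snp$major_allele) hom <- "hom_major"
  else stop("allele '", base, "' is not an allele of ", snp$snp_id)
  m <- counts$counts
  tot <- rowSums(m)
  if (any(tot == 0)) stop("zero genotype total in a group")
  f <- (2 * m[, hom] + m[, "het"]) / (2 * tot)
  pooled <- (2 * sum(m[, hom]) + sum(m[, "het"])) / (2 * sum(m))
  data.frame(group = c(counts$groups, "pooled"), allele = base,
             freq = unname(c(f, pooled)), stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Tests one group's genotype counts against Hardy-Weinberg proportions
#' (p^2, 2pq, q^2) computed from that group's own allele frequency, with a
#' 1-df chi-square (three classes, one estimated allele frequency).
#'
#' @param counts A [genotype_counts()].
#' @param group Group label (a rowname of the counts).
#' @return Object of class `hwe_result`: `group`, `chi2`, `df`, `p_value`,
#'   `expected` (3 expected counts), `degenerate` (TRUE for a monomorphic
#'   SNP, where `chi2 = 0` by convention).
#' @examples
#' cc <- cohort_genotype_counts()[["rs7716600"]]
#' hwe_test(cc, "control")
#' @export
hwe_test <- function(counts, group) {
  stopifnot(inherits(counts, "genotype_counts"), group %in% counts$groups)
  obs <- counts$counts[group, ]
  n <- sum(obs)
  if (n == 0) stop("group '", group, "' has zero total")
  p <- (2 * obs[["hom_major"]] + obs[["het"]]) / (2 * n)
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  degenerate <- p %in% c(0, 1)
  chi2 <- if (degenerate) 0 else sum((obs - expected)^2 / expected)
  structure(list(group = group, chi2 = chi2, df = 1L,
                 p_value = pchisq(chi2, 1, lower.tail = FALSE),
                 expected = unname(expected), observed = unname(obs),
                 degenerate = degenerate),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE [%s]: chi2 = %.4g (df = 1), p = %.4g%s\n", x$group,
              x$chi2, x$p_value, if (x$degenerate) " [monomorphic]" else ""))
  invisible(x)
}

#' Collapse genotype counts under a genetic model
#'
#' Builds the contingency table of one inheritance model.  Class definitions:
#' codominant keeps the three genotypes (hom-major reference); dominant is
#' carrier (het + hom-minor) vs hom-major; recessive is hom-minor vs the
#' rest; overdominant is het vs both homozygotes.  The reference class is
#' always the first row.
#'
#' @param counts A [genotype_counts()].
#' @param model One of `"codominant"`, `"dominant"`, `"recessive"`,
#'   `"overdominant"`.
#' @return Object of class `model_table`: an integer matrix (2 or 3 rows x
#'   2 group columns) with genotype-class rownames, plus attributes `model`
#'   and `snp`.
#' @export
build_model_table <- function(counts, model = c("codominant", "dominant",
                                                "recessive", "overdominant")) {
  stopifnot(inherits(counts, "genotype_counts"))
  model <- match.arg(model)
  cls <- genotype_classes(counts$snp)
  m <- t(counts$counts)   # rows = genotype classes, cols = groups
  tab <- switch(model,
    codominant  = rbind(m["hom_major", ], m["het", ], m["hom_minor", ]),
    dominant    = rbind(m["hom_major", ], m["het", ] + m["hom_minor", ]),
    recessive   = rbind(m["hom_major", ] + m["het", ], m["hom_minor", ]),
    overdominant = rbind(m["hom_major", ] + m["hom_minor", ], m["het", ]))
  rownames(tab) <- switch(model,
    codominant  = unname(cls),
    dominant    = c(cls[["hom_major"]],
                    paste(cls[["het"]], cls[["hom_minor"]], sep = "/")),
    recessive   = c(paste(cls[["hom_major"]], cls[["het"]], sep = "/"),
                    cls[["hom_minor"]]),
    overdominant = c(paste(cls[["hom_major"]], cls[["hom_minor"]], sep = "/"),
                     cls[["het"]]))
  colnames(tab) <- counts$groups
  structure(tab, model = model, snp = counts$snp, class = "model_table")
}

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' The first row of `table` is the reference class, the second the exposure
#' class; columns are the two groups in declared order.  Two orientations are
#' supported.  `outcome = "col2"` (the default) treats membership of the
#' column-2 group as the outcome: `OR = (n2_exp * n1_ref) / (n1_exp * n2_ref)`.
#' This is the convention of the published case-control tables bundled with
#' the package (where controls are column 2).  `outcome = "col1"` is the
#' standard epidemiological orientation (odds of being in column 1 given
#' exposure) and is the reciprocal.  The 95% Wald interval is
#' `exp(log(OR) +/- 1.96 * sqrt(sum(1/cell)))`.  A single zero cell triggers
#' the Haldane-Anscombe correction (+0.5 to all four cells, flagged); two
#' zero cells in one margin leave the OR undefined (an error-flagged result).
#'
#' @param table 2x2 numeric matrix (or a 2-row [build_model_table()] output).
#' @param outcome `"col2"` or `"col1"`.
#' @param conf_level Confidence level for the Wald interval.
#' @return Object of class `association_result` with fields `or_value`,
#'   `ci_lo`, `ci_hi`, `log_se`, `haldane`, `undefined`, `orientation`,
#'   `exposure`, `reference`.
#' @examples
#' tab <- rbind(CC = c(104, 100), `CT/TT` = c(181, 257))
#' odds_ratio(tab)   # OR 1.48 (1.06-2.06)
#' @export
odds_ratio <- function(table, outcome = c("col2", "col1"),
                       conf_level = 0.95) {
  outcome <- match.arg(outcome)
  tab <- unclass(table)
  storage.mode(tab) <- "double"   # avoid integer overflow in cell products
  stopifnot(nrow(tab) == 2L, ncol(tab) == 2L)
  a1 <- tab[1, 1]; a2 <- tab[1, 2]   # reference row
  b1 <- tab[2, 1]; b2 <- tab[2, 2]   # exposure row
  undefined <- (a1 + a2 == 0) || (b1 + b2 == 0) ||
               (a1 + b1 == 0) || (a2 + b2 == 0)
  haldane <- FALSE
  if (!undefined && any(tab == 0)) {
    haldane <- TRUE
    a1 <- a1 + 0.5; a2 <- a2 + 0.5; b1 <- b1 + 0.5; b2 <- b2 + 0.5
  }
  if (undefined) {
    or <- NA_real_; lo <- NA_real_; hi <- NA_real_; se <- NA_real_
  } else {
    or <- (b2 * a1) / (b1 * a2)
    if (outcome == "col1") or <- 1 / or
    se <- sqrt(1 / a1 + 1 / a2 + 1 / b1 + 1 / b2)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo <- exp(log(or) - z * se)
    hi <- exp(log(or) + z * se)
  }
  structure(list(or_value = or, ci_lo = lo, ci_hi = hi, log_se = se,
                 haldane = haldane, undefined = undefined,
                 orientation = outcome,
                 reference = rownames(tab)[1] %||% "ref",
                 exposure = rownames(tab)[2] %||% "exposed"),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("OR [%s vs %s]: undefined (empty margin)\n",
                x$exposure, x$reference))
  } else {
    cat(sprintf("OR [%s vs %s]: %.2f (%.2f-%.2f)%s\n", x$exposure,
                x$reference, round_half_up(x$or_value),
                round_half_up(x$ci_lo), round_half_up(x$ci_hi),
                if (x$haldane) " [Haldane-Anscombe corrected]" else ""))
  }
  invisible(x)
}

#' Likelihood-ratio (G) test of independence
#'
#' Primary association test: `G = 2 * sum(obs * log(obs / exp))` over all
#' cells, with expected counts from the independence margins and
#' `df = (rows - 1) * (cols - 1)`.  Zero observed cells contribute 0 (the
#' limit of `x log x`) and are flagged.  The Pearson chi-square statistic is
#' computed alongside for comparison; no continuity correction is applied.
#'
#' @param table Numeric matrix (2x2 or 3x2 for a codominant block).
#' @return List of class `lr_result`: `g_stat`, `df`, `p_value`,
#'   `pearson_stat`, `pearson_p`, `expected`, `zero_cells`.
#' @examples
#' lr_test(rbind(c(104, 100), c(181, 257)))$p_value   # ~0.022
#' @export
lr_test <- function(table) {
  obs <- unclass(as.matrix(table))
  stopifnot(ncol(obs) >= 2L, nrow(obs) >= 2L)
  n <- sum(obs)
  if (n == 0 || any(rowSums(obs) == 0) || any(colSums(obs) == 0))
    stop("degenerate table: empty margin")
  expected <- outer(rowSums(obs), colSums(obs)) / n
  zero_cells <- sum(obs == 0)
  terms <- ifelse(obs > 0, obs * log(obs / expected), 0)
  g <- 2 * sum(terms)
  pearson <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  structure(list(g_stat = g, df = df,
                 p_value = pchisq(g, df, lower.tail = FALSE),
                 pearson_stat = pearson,
                 pearson_p = pchisq(pearson, df, lower.tail = FALSE),
                 expected = expected, zero_cells = zero_cells),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("G = %.4g (df = %d), p = %.4g  [Pearson X2 = %.4g, p = %.4g]\n",
              x$g_stat, x$df, x$p_value, x$pearson_stat, x$pearson_p))
  invisible(x)
}

#' Run all four genetic models for one SNP
#'
#' Produces one association block per inheritance model (codominant,
#' dominant, recessive, overdominant) in the layout of a published
#' case-control table: per-row odds ratios with Wald CIs against the model's
#' reference class and one likelihood-ratio p-value per model block, plus
#' Hardy-Weinberg results for both groups.  No multiple-testing adjustment is
#' applied; the number of model tests run is recorded in `n_tests`.
#'
#' @param x A [genotype_counts()] object, or a [genotype_dataset()] (in which
#'   case `snp_id` and `group_pair` select and count the data first).
#' @param ... Passed to methods.
#' @return Object of class `model_results`: list with `snp`, `groups`,
#'   `counts`, `hwe` (list of two [hwe_test()] results), `results` (a
#'   `data.frame` with one row per exposure class: `model`, `exposure`,
#'   `reference`, `n_1`, `n_2`, `or`, `ci_lo`, `ci_hi`, `p_lr`, `p_pearson`),
#'   and `n_tests`.
#' @examples
#' run_models(cohort_genotype_counts()[["rs4415084"]])
#' @export
run_models <- function(x, ...) UseMethod("run_models")

#' @rdname run_models
#' @param outcome OR orientation, see [odds_ratio()].
#' @export
run_models.genotype_counts <- function(x, outcome = c("col2", "col1"), ...) {
  outcome <- match.arg(outcome)
  models <- c("codominant", "dominant", "recessive", "overdominant")
  rows <- list()
  for (mod in models) {
    tab <- build_model_table(x, mod)
    lr <- lr_test(tab)
    nr <- nrow(tab)
    for (i in 2:nr) {
      orr <- odds_ratio(unclass(tab)[c(1, i), , drop = FALSE],
                        outcome = outcome)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod, exposure = rownames(tab)[i], reference = rownames(tab)[1],
        n_1 = tab[i, 1], n_2 = tab[i, 2],
        or = orr$or_value, ci_lo = orr$ci_lo, ci_hi = orr$ci_hi,
        p_lr = lr$p_value, p_pearson = lr$pearson_p,
        haldane = orr$haldane, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  structure(list(snp = x$snp, groups = x$groups, counts = x,
                 hwe = setNames(lapply(x$groups, hwe_test, counts = x),
                                x$groups),
                 results = res, orientation = outcome,
                 n_tests = length(models)),
            class = "model_results")
}

#' @rdname run_models
#' @param snp_id rsID to analyse.
#' @param group_pair Two group labels (column order).
#' @param minor_from See [count_genotypes()].
#' @export
run_models.genotype_dataset <- function(x, snp_id,
                                        group_pair = unique(x$samples$group),
                                        outcome = c("col2", "col1"),
                                        minor_from = "pooled", ...) {
  cc <- count_genotypes(x, snp_id, group_pair, minor_from = minor_from)
  run_models(cc, outcome = outcome)
}

#' @export
print.model_results <- function(x, ...) {
  cat(render_table(x), sep = "\n")
  invisible(x)
}
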