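#' Specify a synthetic case-control genotype cohort
#'
#' Defines the generating distribution for [gen_cohort()].  Each SNP is
#' specified either by a minor allele frequency (genotypes drawn under
#' Hardy-Weinberg proportions, shared across groups) or by explicit per-group
#' genotype probabilities (hom-major, het, hom-minor), which makes expected
#' odds ratios analytic.  Missingness is applied after the genotype draw,
#' independently per sample, at a per-SNP per-group rate.
#'
#' @param n_per_group Named integer vector of group sizes, e.g.
#'   `c(case = 291, control = 370)`.
#' @param snp_specs Named list (by rsID).  Each element is a list with the
#'   [snp_def()] under `snp` and either `maf` (scalar in (0, 0.5]) or
#'   `probs` (matrix groups x 3, rows summing to 1).  Optional `missing`
#'   is a named vector of per-group missing rates in [0, 1).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return Object of class `cohort_spec`.
#' @examples
#' snp <- snp_def("rs0001", "chr1", 100, "A", "G")
#' spec <- cohort_spec(c(case = 50, control = 50),
#'                     list(rs0001 = list(snp = snp, maf = 0.3)), seed = 1)
#' @export
cohort_spec <- function(n_per_group, snp_specs, seed = 1L) {
  stopifnot(length(n_per_group) >= 2L, !is.null(names(n_per_group)),
            all(n_per_group >= 1))
  for (id in names(snp_specs)) {
    s <- snp_specs[[id]]
    stopifnot(inherits(s$snp, "snp_def"))
    if (!is.null(s$maf)) {
      if (s$maf <= 0 || s$maf > 0.5)
        stop("maf for ", id, " must be in (0, 0.5]")
    } else if (!is.null(s$probs)) {
      p <- as.matrix(s$probs)
      if (ncol(p) != 3L || !all(rownames(p) %in% names(n_per_group)))
        stop("probs for ", id, " must be a groups x 3 matrix")
      if (any(abs(rowSums(p) - 1) > 1e-8))
        stop("genotype probabilities for ", id, " must sum to 1 per group")
      if (any(p < 0)) stop("negative genotype probability for ", id)
    } else stop("snp spec for ", id, " needs 'maf' or 'probs'")
    if (!is.null(s$missing) && any(s$missing < 0 | s$missing >= 1))
      stop("missing rates for ", id, " must be in [0, 1)")
  }
  structure(list(n_per_group = n_per_group, snp_specs = snp_specs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic genotype cohort
#'
#' Draws genotypes independently per sample from the distribution in a
#' [cohort_spec()], applies missingness, and returns a [genotype_dataset()].
#'
#' @param spec A [cohort_spec()].
#' @return A [genotype_dataset()] with groups and SNPs as specified.
#' @examples
#' snp <- snp_def("rs0001", "chr1", 100, "A", "G")
#' d <- gen_cohort(cohort_spec(c(case = 30, control = 30),
#'                 list(rs0001 = list(snp = snp, maf = 0.25)), seed = 7))
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(sub_seed(spec$seed, 101L))
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  samples <- data.frame(sample_id = sprintf("SYN%05d", seq_len(n)),
                        group = groups, stringsAsFactors = FALSE)
  gmat <- matrix(NA_character_, n, length(spec$snp_specs),
                 dimnames = list(samples$sample_id, names(spec$snp_specs)))
  for (id in names(spec$snp_specs)) {
    s <- spec$snp_specs[[id]]
    cls <- genotype_classes(s$snp)
    for (g in names(spec$n_per_group)) {
      idx <- which(groups == g)
      p <- if (!is.null(s$maf)) {
        q <- s$maf
        c((1 - q)^2, 2 * q * (1 - q), q^2)
      } else as.numeric(s$probs[g, ])
      draw <- sample.int(3L, length(idx), replace = TRUE, prob = p)
      gt <- cls[draw]
      mr <- if (!is.null(s$missing)) (s$missing[g] %||% 0) else 0
      mr <- if (is.na(mr)) 0 else as.numeric(mr)
      if (mr > 0) gt[runif(length(idx)) < mr] <- NA_character_
      gmat[idx, id] <- gt
    }
  }
  ds <- genotype_dataset(samples, gmat,
                         lapply(spec$snp_specs, `[[`, "snp"),
                         build = spec$snp_specs[[1]]$snp$build)
  ds
}

#' Specify a two-locus haplotype population
#'
#' @param haplotype_freqs Either a numeric vector of 4 frequencies (order
#'   A1B1, A1B2, A2B1, A2B2; shared by all groups) or a matrix with one such
#'   row per group (rownames = group names).  Rows must be non-negative and
#'   sum to 1 (tolerance 1e-8).
#' @param n_per_group Named integer vector of group sizes.
#' @param snp_a,snp_b [snp_def()]s of the two loci (allele 1 = major).
#' @param seed Integer seed.
#' @return Object of class `two_locus_spec`.
#' @export
two_locus_spec <- function(haplotype_freqs, n_per_group, snp_a, snp_b,
                           seed = 1L) {
  stopifnot(inherits(snp_a, "snp_def"), inherits(snp_b, "snp_def"),
            !is.null(names(n_per_group)), all(n_per_group >= 1))
  f <- if (is.matrix(haplotype_freqs)) haplotype_freqs
       else matrix(haplotype_freqs, nrow = length(n_per_group), ncol = 4,
                   byrow = TRUE, dimnames = list(names(n_per_group), NULL))
  if (ncol(f) != 4L || !all(rownames(f) %in% names(n_per_group)))
    stop("haplotype_freqs must give 4 frequencies per group")
  if (any(f < 0)) stop("haplotype frequencies must be >= 0")
  if (any(abs(rowSums(f) - 1) > 1e-8))
    stop("haplotype frequencies must sum to 1 per group")
  structure(list(haplotype_freqs = f, n_per_group = n_per_group,
                 snp_a = snp_a, snp_b = snp_b, seed = as.integer(seed)),
            class = "two_locus_spec")
}

#' Generate a two-locus cohort from haplotype frequencies
#'
#' Each individual receives two haplotypes drawn i.i.d. from their group's
#' haplotype distribution.  Downstream analyses see only the unphased
#' genotype pair; the true phased haplotype draw is retained in an audit
#' attribute (`attr(x, "true_haplotypes")`, an n x 2 matrix of haplotype
#' indices 1-4) for tests.
#'
#' @param spec A [two_locus_spec()].
#' @return A [genotype_dataset()] with the two SNPs.
#' @export
gen_two_locus <- function(spec) {
  stopifnot(inherits(spec, "two_locus_spec"))
  set.seed(sub_seed(spec$seed, 202L))
  da <- spec$snp_a; db <- spec$snp_b
  hap_a <- c(da$major_allele, da$major_allele, da$minor_allele,
             da$minor_allele)
  hap_b <- c(db$major_allele, db$minor_allele, db$major_allele,
             db$minor_allele)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  h1 <- integer(n); h2 <- integer(n)
  for (g in names(spec$n_per_group)) {
    idx <- which(groups == g)
    f <- spec$haplotype_freqs[g, ]
    h1[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = f)
    h2[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = f)
  }
  ga <- normalize_genotype(paste0(hap_a[h1], hap_a[h2]))
  gb <- normalize_genotype(paste0(hap_b[h1], hap_b[h2]))
  samples <- data.frame(sample_id = sprintf("TL%05d", seq_len(n)),
                        group = groups, stringsAsFactors = FALSE)
  gmat <- cbind(ga, gb)
  colnames(gmat) <- c(da$snp_id, db$snp_id)
  rownames(gmat) <- samples$sample_id
  ds <- genotype_dataset(samples, gmat, list(da, db), build = da$build)
  attr(ds, "true_haplotypes") <- cbind(h1, h2)
  ds
}

#' Specify a synthetic expression matrix
#'
#' Gene values are drawn as `2^(baseline + log2fc * I(group == tumor_group) +
#' subtype effects + Gaussian noise)`, emulating positive FPKM-like
#' expression with planted log2 fold changes.
#'
#' @param n_genes Number of genes (>= 1); gene ids `gene_1`, `gene_2`, ...
#' @param group_sizes Named vector, e.g. `c(tumor = 100, normal = 100)`.
#' @param tumor_group Name of the group receiving the planted fold change.
#' @param log2fc Numeric vector (length `n_genes`, recycled) of planted
#'   tumor-vs-normal log2 fold changes.
#' @param subtype_log2fc Optional matrix genes x subtypes of planted
#'   subtype-vs-rest log2 fold changes (tumor samples only).
#' @param subtypes Optional named vector of subtype proportions for tumor
#'   samples (must sum to 1), e.g. `c(lumA = 0.5, her2 = 0.2, basal = 0.3)`.
#' @param baseline Per-gene baseline log2 expression (recycled); default
#'   draws once from Unif(1, 8).
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0).
#' @param seed Integer seed.
#' @return Object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes, group_sizes, log2fc = 0,
                            tumor_group = names(group_sizes)[1],
                            subtype_log2fc = NULL, subtypes = NULL,
                            baseline = NULL, noise_sd = 1, seed = 1L) {
  stopifnot(n_genes >= 1, noise_sd > 0, length(group_sizes) >= 2L,
            tumor_group %in% names(group_sizes))
  if (!is.null(subtypes) && abs(sum(subtypes) - 1) > 1e-8)
    stop("subtype proportions must sum to 1")
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 tumor_group = tumor_group,
                 log2fc = rep_len(log2fc, n_genes),
                 subtype_log2fc = subtype_log2fc, subtypes = subtypes,
                 baseline = baseline, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate a synthetic expression table
#'
#' @param spec An [expression_spec()].
#' @return List of class `expression_table`: `values` (genes x samples
#'   matrix, linear scale, >= 0), `samples` (`data.frame` with `sample_id`,
#'   `group` and, when subtypes are specified, `subtype`), and `truth`
#'   (`data.frame` with the planted `log2fc` per gene).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  set.seed(sub_seed(spec$seed, 303L))
  genes <- sprintf("gene_%d", seq_len(spec$n_genes))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(groups)
  samples <- data.frame(sample_id = sprintf("EX%05d", seq_len(n)),
                        group = groups, stringsAsFactors = FALSE)
  is_tumor <- groups == spec$tumor_group
  if (!is.null(spec$subtypes)) {
    samples$subtype <- NA_character_
    samples$subtype[is_tumor] <- sample(names(spec$subtypes),
                                        sum(is_tumor), replace = TRUE,
                                        prob = spec$subtypes)
  }
  base <- spec$baseline %||% runif(spec$n_genes, 1, 8)
  base <- rep_len(base, spec$n_genes)
  logx <- matrix(base, spec$n_genes, n) +
    outer(spec$log2fc, as.numeric(is_tumor)) +
    matrix(rnorm(spec$n_genes * n, sd = spec$noise_sd), spec$n_genes, n)
  if (!is.null(spec$subtype_log2fc) && !is.null(spec$subtypes)) {
    for (st in colnames(spec$subtype_log2fc)) {
      in_st <- !is.na(samples$subtype) & samples$subtype == st
      logx[, in_st] <- logx[, in_st] + spec$subtype_log2fc[, st]
    }
  }
  values <- 2^logx
  dimnames(values) <- list(genes, samples$sample_id)
  structure(list(values = values, samples = samples,
                 truth = data.frame(gene = genes, log2fc = spec$log2fc,
                                    stringsAsFactors = FALSE)),
            class = "expression_table")
}

#' Generate GWAS-catalog-like records with controlled placement
#'
#' Builds a list of [gwas_record()]s carrying stated odds ratios and minor
#' allele frequencies, positioned inside or outside a set of lncRNA
#' intervals as requested — a controllable fixture for the selection
#' pipeline.
#'
#' @param snp_ids Character vector of rsIDs.
#' @param or_values,mafs Numeric vectors parallel to `snp_ids`.
#' @param intervals List of [lnc_interval()]s used for placement.
#' @param placement Character vector (`"inside"`/`"outside"`, recycled):
#'   whether each SNP's position falls within some interval.
#' @param trait Trait string stored on each record.
#' @param seed Integer seed (positions inside an interval are drawn
#'   uniformly within it).
#' @return List of [gwas_record()]s.
#' @export
gen_gwas_records <- function(snp_ids, or_values, mafs, intervals,
                             placement = "inside", trait = "breast carcinoma",
                             seed = 1L) {
  if (length(or_values) != length(snp_ids) || length(mafs) != length(snp_ids))
    stop("snp_ids, or_values and mafs must have equal length")
  set.seed(sub_seed(seed, 404L))
  placement <- rep_len(placement, length(snp_ids))
  max_end <- max(vapply(intervals, `[[`, 0, "end"))
  records <- vector("list", length(snp_ids))
  for (i in seq_along(snp_ids)) {
    if (placement[i] == "inside") {
      iv <- intervals[[1 + (i - 1) %% length(intervals)]]
      pos0 <- iv$start + sample.int(iv$end - iv$start, 1L) - 1L
      chrom <- iv$chrom
    } else {
      pos0 <- max_end + 10000L * i   # beyond every interval
      chrom <- intervals[[1]]$chrom
    }
    records[[i]] <- gwas_record(snp_id = snp_ids[i], chrom = chrom,
                                pos = pos0 + 1L,  # record positions are 1-based
                                trait = trait, reported_or = or_values[i],
                                maf = mafs[i])
  }
  records
}
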