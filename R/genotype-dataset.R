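#' Construct a genotype dataset
#'
#' The central container for case-control genotype data: a sample table
#' (sample id, group label, clinical covariates), an unphased genotype matrix
#' (samples x SNPs, normalized two-character strings or `NA` for missing) and
#' the SNP definitions.  Every analysis in the package is complete-case per
#' SNP: each SNP is analyzed on its non-missing samples, so per-SNP sample
#' sizes may differ.
#'
#' @param samples `data.frame` with at least `sample_id` and `group` columns;
#'   any further columns are treated as clinical covariates.
#' @param genotypes Character matrix, rows = samples, columns = SNPs (column
#'   names must match the `snp_id`s of `snp_defs`).  Entries are genotype
#'   strings (normalized on construction) or `NA`.
#' @param snp_defs List of [snp_def()] objects.
#' @param build Genome build label, carried as metadata.
#'
#' @return An object of class `genotype_dataset`.
#' @seealso [read_genotype_table()], [gen_cohort()], [count_genotypes()]
#' @export
genotype_dataset <- function(samples, genotypes, snp_defs,
                             build = NA_character_) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("sample_ids must be unique")
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  mode(genotypes) <- "character"
  names(snp_defs) <- vapply(snp_defs, `[[`, "", "snp_id")
  if (is.null(colnames(genotypes)) ||
      !setequal(colnames(genotypes), names(snp_defs)))
    stop("genotype matrix columns must match snp_def ids")
  genotypes <- genotypes[, names(snp_defs), drop = FALSE]
  rownames(genotypes) <- samples$sample_id
  for (id in names(snp_defs)) {
    genotypes[, id] <- normalize_genotype(genotypes[, id])
    bad <- !is.na(genotypes[, id]) &
      !(genotypes[, id] %in% genotype_classes(snp_defs[[id]]))
    if (any(bad))
      stop("invalid genotype(s) for ", id, " in sample(s) ",
           paste(head(samples$sample_id[bad], 5), collapse = ", "),
           ": allele not in {", snp_defs[[id]]$major_allele, ",",
           snp_defs[[id]]$minor_allele, "}")
  }
  structure(
    list(samples = samples, genotypes = genotypes, snp_defs = snp_defs,
         build = build),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d samples x %d SNPs\n",
              nrow(x$samples), length(x$snp_defs)))
  print(table(x$samples$group))
  mc <- missing_counts(x)
  if (any(mc$n_missing > 0)) {
    cat("missing genotypes per SNP/group:\n")
    print(mc[mc$n_missing > 0, ])
  }
  invisible(x)
}

#' Per-SNP, per-group missing genotype counts
#'
#' @param dataset A [genotype_dataset()].
#' @return `data.frame` with columns `snp_id`, `group`, `n_missing`, `n_total`.
#' @export
missing_counts <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  groups <- unique(dataset$samples$group)
  out <- expand.grid(snp_id = names(dataset$snp_defs), group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_missing <- mapply(function(id, g) {
    sum(is.na(dataset$genotypes[dataset$samples$group == g, id]))
  }, out$snp_id, out$group)
  out$n_total <- vapply(out$group,
                        function(g) sum(dataset$samples$group == g), 0L)
  out
}

#' Expand a genotype-counts table into an individual-level dataset
#'
#' Deterministically constructs a [genotype_dataset()] whose per-group genotype
#' counts reproduce `counts` exactly.  Useful for re-running individual-level
#' analyses (stratification, model fitting) from published count tables.
#'
#' @param counts A [genotype_counts()] object.
#' @param clinical_name If `NULL` (default) the two count groups become the
#'   dataset's `group` labels.  If a string, all samples are labelled
#'   `case_label` and the count groups instead populate a clinical column of
#'   this name (e.g. `"pr_status"`), ready for [stratify()].
#' @param case_label Group label used when `clinical_name` is given.
#' @return A [genotype_dataset()] with one SNP.
#' @examples
#' cc <- cohort_genotype_counts()[["rs4415084"]]
#' d <- dataset_from_counts(cc)
#' count_genotypes(d, "rs4415084", group_pair = c("case", "control"))
#' @export
dataset_from_counts <- function(counts, clinical_name = NULL,
                                case_label = "case") {
  stopifnot(inherits(counts, "genotype_counts"))
  snp <- counts$snp
  cls <- genotype_classes(snp)
  groups <- rownames(counts$counts)
  gt <- character(0); grp <- character(0)
  for (g in groups) for (k in 1:3) {
    n <- counts$counts[g, k]
    gt <- c(gt, rep(cls[[k]], n)); grp <- c(grp, rep(g, n))
  }
  samples <- data.frame(sample_id = sprintf("S%04d", seq_along(gt)),
                        group = grp, stringsAsFactors = FALSE)
  if (!is.null(clinical_name)) {
    samples[[clinical_name]] <- samples$group
    samples$group <- case_label
  }
  m <- matrix(gt, ncol = 1, dimnames = list(samples$sample_id, snp$snp_id))
  genotype_dataset(samples, m, list(snp), build = snp$build)
}
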