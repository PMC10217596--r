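#' Selection pipeline configuration
#'
#' Thresholds of the three-stage candidate filter.  `fc_threshold` is a
#' LINEAR fold change: a gene passes when `|log2fc| > log2(fc_threshold)`,
#' so the default 1.5 keeps e.g. `log2fc = 0.87` (linear 1.83).  The MAF
#' filter is strict (`maf > maf_threshold`): a frequency exactly at the
#' threshold is excluded as rare.  No multiple-testing correction is applied
#' to the raw DE p-value cut.
#'
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param de_p_threshold DE p-value threshold (default 0.001).
#' @param maf_threshold Minor-allele-frequency threshold (default 0.20).
#' @param n_select Number of distinct SNPs to pick by descending OR.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(fc_threshold = 1.5, de_p_threshold = 0.001,
                             maf_threshold = 0.20, n_select = 4L) {
  stopifnot(fc_threshold > 0, de_p_threshold > 0, maf_threshold > 0,
            n_select >= 1)
  structure(list(fc_threshold = fc_threshold,
                 de_p_threshold = de_p_threshold,
                 maf_threshold = maf_threshold,
                 n_select = as.integer(n_select)),
            class = "selection_config")
}

#' Tumor-vs-normal differential expression
#'
#' Per gene: `log2fc = mean(log2(x + 1) in group_a) - mean(log2(x + 1) in
#' group_b)` and a two-sample unequal-variance (Welch) t-test on the
#' `log2(x + 1)` values.  Genes with identical values in both groups get
#' `log2fc = 0, p = 1`.  The test is deliberately isolated here so an
#' alternative DE method can be swapped in.
#'
#' @param expr An `expression_table` (see [gen_expression()]) or a genes x
#'   samples matrix.
#' @param group_a,group_b Group labels (`a` minus `b`); each needs >= 2
#'   samples.
#' @param samples Sample `data.frame` (required when `expr` is a bare
#'   matrix).
#' @return `data.frame` with `gene`, `log2fc`, `p_value`.
#' @export
compute_de <- function(expr, group_a, group_b, samples = NULL) {
  if (inherits(expr, "expression_table")) {
    samples <- expr$samples
    expr <- expr$values
  }
  stopifnot(is.matrix(expr), !is.null(samples))
  if (any(expr < 0)) stop("expression values must be >= 0")
  ia <- samples$group == group_a
  ib <- samples$group == group_b
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop("each group needs >= 2 samples (variance undefined)")
  la <- log2(expr[, ia, drop = FALSE] + 1)
  lb <- log2(expr[, ib, drop = FALSE] + 1)
  log2fc <- rowMeans(la) - rowMeans(lb)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    t.test(xa, xb)$p.value
  }, 0)
  data.frame(gene = rownames(expr) %||% sprintf("gene_%d", seq_along(p)),
             log2fc = unname(log2fc), p_value = p, stringsAsFactors = FALSE)
}

#' Subtype differential-expression flags
#'
#' For each molecular subtype, tests subtype vs all other tumor samples with
#' the same Welch test and thresholds as [compute_de()], flagging each gene
#' `"up"`, `"down"` or `"ns"` per subtype.
#'
#' @param expr An `expression_table` with a `subtype` column in its samples.
#' @param config A [selection_config()] supplying the thresholds.
#' @return `data.frame`, genes x subtypes, of `"up"`/`"down"`/`"ns"` flags.
#' @export
compute_subtype_flags <- function(expr, config = selection_config()) {
  stopifnot(inherits(expr, "expression_table"),
            "subtype" %in% names(expr$samples))
  tum <- !is.na(expr$samples$subtype)
  vals <- expr$values[, tum, drop = FALSE]
  st <- expr$samples$subtype[tum]
  subtypes <- sort(unique(st))
  lfc_cut <- log2(config$fc_threshold)
  out <- matrix("ns", nrow(vals), length(subtypes),
                dimnames = list(rownames(vals), subtypes))
  for (s in subtypes) {
    fake_samples <- data.frame(sample_id = colnames(vals),
                               group = ifelse(st == s, s, "rest"),
                               stringsAsFactors = FALSE)
    de <- compute_de(vals, s, "rest", samples = fake_samples)
    up <- de$log2fc > lfc_cut & de$p_value < config$de_p_threshold
    dn <- de$log2fc < -lfc_cut & de$p_value < config$de_p_threshold
    out[up, s] <- "up"; out[dn, s] <- "down"
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Filter DE results on fold change and p-value
#'
#' Keeps genes with `|log2fc| > log2(fc_threshold)` AND
#' `p_value < de_p_threshold`.  Down-regulated genes pass on absolute fold
#' change.
#'
#' @param de `data.frame` from [compute_de()] (columns `log2fc`, `p_value`).
#' @param config A [selection_config()].
#' @return The kept subset of `de`.
#' @export
filter_de <- function(de, config = selection_config()) {
  keep <- abs(de$log2fc) > log2(config$fc_threshold) &
    de$p_value < config$de_p_threshold
  de[keep, , drop = FALSE]
}

#' Pair GWAS SNPs with the lncRNA intervals containing them
#'
#' A SNP is paired with an interval when its position (converted from
#' 1-based to a 0-based point) lies in `[start, end)` — a SNP exactly at the
#' end coordinate is outside.  A SNP inside two overlapping lncRNAs yields
#' two pairs.  Overlap ignores strand.  Records and intervals carrying
#' different (non-missing) genome builds raise an error instead of silently
#' mixing coordinates.
#'
#' @param gwas_records List of [gwas_record()]s.
#' @param intervals List of [lnc_interval()]s.
#' @return `data.frame` with one row per (SNP, interval) pair: `snp_id`,
#'   `chrom`, `pos`, `reported_or`, `maf`, `trait`, `lncrna`, `start`, `end`.
#' @export
intersect_snps_lncrnas <- function(gwas_records, intervals) {
  builds <- unique(stats::na.omit(c(
    vapply(gwas_records, `[[`, "", "build"),
    vapply(intervals, `[[`, "", "build"))))
  if (length(builds) > 1L)
    stop("genome build mismatch: ", paste(builds, collapse = " vs "))
  if (length(gwas_records) == 0L || length(intervals) == 0L)
    return(empty_pair_frame())
  # GRanges is 1-based closed: BED [start, end) -> [start+1, end];
  # a 1-based SNP position p is the 0-based point p-1, inside iff
  # start+1 <= p <= end.
  iv <- GenomicRanges::GRanges(
    seqnames = vapply(intervals, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(intervals, `[[`, 0, "start") + 1,
      end = vapply(intervals, `[[`, 0, "end")))
  sn <- GenomicRanges::GRanges(
    seqnames = vapply(gwas_records, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(gwas_records, `[[`, 0, "pos"), width = 1))
  hits <- GenomicRanges::findOverlaps(sn, iv, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty_pair_frame())
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  do.call(rbind, lapply(seq_along(qi), function(k) {
    r <- gwas_records[[qi[k]]]; v <- intervals[[si[k]]]
    data.frame(snp_id = r$snp_id, chrom = r$chrom, pos = r$pos,
               reported_or = r$reported_or, maf = r$maf, trait = r$trait,
               lncrna = v$name, start = v$start, end = v$end,
               stringsAsFactors = FALSE)
  }))
}

empty_pair_frame <- function() {
  data.frame(snp_id = character(), chrom = character(), pos = numeric(),
             reported_or = numeric(), maf = numeric(), trait = character(),
             lncrna = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

#' Filter SNP/lncRNA pairs on minor allele frequency
#'
#' Keeps pairs with `maf > maf_threshold` (strict: a SNP at exactly the
#' threshold is excluded as rare).
#'
#' @param pairs `data.frame` from [intersect_snps_lncrnas()] (needs a `maf`
#'   column).
#' @param config A [selection_config()].
#' @return The kept subset.
#' @export
filter_maf <- function(pairs, config = selection_config()) {
  pairs[pairs$maf > config$maf_threshold, , drop = FALSE]
}

#' Filter candidates on subtype differential expression
#'
#' Keeps candidate rows whose host lncRNA is differentially expressed in at
#' least one molecular subtype, i.e. has at least one non-`"ns"` subtype
#' flag.
#'
#' @param candidates `data.frame` with a `subtype_flags` character column
#'   (comma-separated `subtype=up/down` entries, `""` or `"ns"` when none).
#' @return The kept subset.
#' @export
filter_subtype_de <- function(candidates) {
  flags <- candidates$subtype_flags
  has_flag <- !is.na(flags) & nzchar(flags) &
    vapply(strsplit(flags, ","), function(fl) {
      any(!grepl("(=|^)ns$", trimws(fl)) & nzchar(trimws(fl)))
    }, TRUE)
  candidates[has_flag, , drop = FALSE]
}

#' Select top SNPs by reported odds ratio
#'
#' Sorts candidate rows by reported OR descending and takes rows until
#' `n_select` distinct SNPs are collected; a row may carry several SNPs
#' (slash-separated rsIDs, e.g. two SNPs tagging the same lncRNA).  Rows
#' with equal OR are taken in rsID-lexicographic order, and any tie-break is
#' recorded in attribute `tie_break` and messaged.  Requesting more SNPs
#' than available returns all of them with a warning.
#'
#' @param candidates `data.frame` with `snp_id` (possibly slash-separated)
#'   and `reported_or`.
#' @param config A [selection_config()] (uses `n_select`).
#' @return Character vector of selected rsIDs (attribute `tie_break` is TRUE
#'   if a tie was broken).
#' @export
rank_select <- function(candidates, config = selection_config()) {
  stopifnot(all(c("snp_id", "reported_or") %in% names(candidates)))
  ord <- order(-candidates$reported_or, candidates$snp_id)
  cand <- candidates[ord, , drop = FALSE]
  tie <- anyDuplicated(candidates$reported_or) > 0
  if (tie) message("rank_select: equal ORs present; ",
                   "ties broken by rsID lexicographic order")
  selected <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (length(selected) >= config$n_select) break
    selected <- unique(c(selected,
                         strsplit(cand$snp_id[i], "/", fixed = TRUE)[[1]]))
  }
  if (length(selected) < config$n_select)
    warning("only ", length(selected), " SNP(s) available; n_select = ",
            config$n_select)
  structure(selected, tie_break = tie)
}

#' Run the full candidate-selection pipeline
#'
#' Chains the three filters: (1) tumor-vs-normal DE (fold change and
#' p-value), (2) GWAS/interval intersection with the MAF filter, (3) subtype
#' DE — then ranks survivors by reported OR.  Every candidate row carries its
#' full flag trail (`pass_de`, `pass_maf`, `pass_subtype`); the filters have
#' set-intersection semantics, so their order does not change the result.
#'
#' @param de `data.frame` from [compute_de()] plus a `subtype_flags` column
#'   (see [compute_subtype_flags()]) and a `gene` column naming the host
#'   lncRNA.
#' @param gwas_records List of [gwas_record()]s.
#' @param intervals List of [lnc_interval()]s (names must match DE genes for
#'   a candidate to form).
#' @param config A [selection_config()].
#' @return List of class `candidate_selection`: `candidates` (all
#'   DE-gene/SNP pairings with flag columns), `surviving` (rows passing all
#'   three filters) and `selected` (rsIDs picked by [rank_select()]).
#' @export
select_candidates <- function(de, gwas_records, intervals,
                              config = selection_config()) {
  pairs <- intersect_snps_lncrnas(gwas_records, intervals)
  merged <- merge(pairs, de, by.x = "lncrna", by.y = "gene")
  if (!"subtype_flags" %in% names(merged)) merged$subtype_flags <- ""
  merged$pass_de <- abs(merged$log2fc) > log2(config$fc_threshold) &
    merged$p_value < config$de_p_threshold
  merged$pass_maf <- merged$maf > config$maf_threshold
  merged$pass_subtype <- rownames(merged) %in%
    rownames(filter_subtype_de(merged))
  surviving <- merged[merged$pass_de & merged$pass_maf & merged$pass_subtype,
                      , drop = FALSE]
  selected <- if (nrow(surviving)) rank_select(surviving, config)
              else character(0)
  structure(list(candidates = merged, surviving = surviving,
                 selected = selected, config = config),
            class = "candidate_selection")
}

#' @export
print.candidate_selection <- function(x, ...) {
  cat(sprintf("<candidate_selection> %d pairings, %d pass all filters\n",
              nrow(x$candidates), nrow(x$surviving)))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
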