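#' Define a clinical stratification rule
#'
#' Three rule types cover the usual clinical covariates of a tumor cohort:
#' `dichotomize_at_mean` splits a numeric variable at a cutoff (values equal
#' to the cutoff go to the "higher" stratum); `binary_status` uses a
#' negative/positive factor (receptor status, lymph-node involvement), with
#' the negative stratum as column 1; `ordinal_levels` keeps ordered levels
#' (e.g. tumor grade I/II/III) with the first level as reference.
#'
#' @param variable Clinical column name in the dataset's sample table.
#' @param rule One of `"dichotomize_at_mean"`, `"binary_status"`,
#'   `"ordinal_levels"`.
#' @param cutoff Numeric cutoff for `dichotomize_at_mean`; if `NULL`, the
#'   mean of the non-missing case values is used.
#' @param levels For `binary_status`, the two status values in
#'   (negative, positive) order; for `ordinal_levels`, the ordered level
#'   values (reference first).
#' @return Object of class `stratum_rule`.
#' @examples
#' stratum_rule("pr_status", "binary_status",
#'              levels = c("negative", "positive"))
#' stratum_rule("age", "dichotomize_at_mean", cutoff = 57.90)
#' @export
stratum_rule <- function(variable,
                         rule = c("dichotomize_at_mean", "binary_status",
                                  "ordinal_levels"),
                         cutoff = NULL, levels = NULL) {
  rule <- match.arg(rule)
  if (rule == "binary_status" && !is.null(levels) && length(levels) != 2L)
    stop("binary_status needs exactly two levels (negative, positive)")
  if (rule == "ordinal_levels" && (is.null(levels) || length(levels) < 2L))
    stop("ordinal_levels needs >= 2 ordered levels")
  structure(list(variable = variable, rule = rule, cutoff = cutoff,
                 levels = levels),
            class = "stratum_rule")
}

#' Stratify case samples by a clinical rule
#'
#' Restricts the dataset to case samples, replaces the group label by the
#' stratum label, and drops samples with a missing clinical value (the count
#' is messaged and stored in attribute `n_dropped`).  Controls never enter a
#' stratified analysis.  An empty stratum is an error naming the stratum.
#'
#' @param dataset A [genotype_dataset()].
#' @param rule A [stratum_rule()].
#' @param case_group Label of the case group (default `"case"`).
#' @return A [genotype_dataset()] of cases only, with stratum labels as
#'   groups and attribute `stratum_levels` giving the column order.
#' @export
stratify <- function(dataset, rule, case_group = "case") {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(rule, "stratum_rule"))
  if (!rule$variable %in% names(dataset$samples))
    stop("clinical variable '", rule$variable, "' not in dataset")
  cases <- dataset$samples$group == case_group
  if (!any(cases)) stop("no samples in case group '", case_group, "'")
  v <- dataset$samples[[rule$variable]][cases]
  lab <- switch(rule$rule,
    dichotomize_at_mean = {
      v <- as.numeric(v)
      cutoff <- rule$cutoff %||% mean(v, na.rm = TRUE)
      ifelse(is.na(v), NA_character_,
             ifelse(v >= cutoff, "higher", "lower"))  # boundary -> higher
    },
    binary_status = {
      lv <- rule$levels %||% c("negative", "positive")
      ifelse(v %in% lv, as.character(v), NA_character_)
    },
    ordinal_levels = {
      ifelse(v %in% rule$levels, as.character(v), NA_character_)
    })
  levels_out <- switch(rule$rule,
    dichotomize_at_mean = c("lower", "higher"),
    binary_status = rule$levels %||% c("negative", "positive"),
    ordinal_levels = rule$levels)
  n_dropped <- sum(is.na(lab))
  if (n_dropped > 0)
    message("stratify: dropped ", n_dropped,
            " case(s) with missing '", rule$variable, "'")
  keep_idx <- which(cases)[!is.na(lab)]
  lab <- lab[!is.na(lab)]
  empty <- setdiff(levels_out, unique(lab))
  if (length(empty))
    stop("stratum with zero members: ", paste(empty, collapse = ", "))
  samples <- dataset$samples[keep_idx, , drop = FALSE]
  samples$group <- lab
  out <- genotype_dataset(samples,
                          dataset$genotypes[keep_idx, , drop = FALSE],
                          dataset$snp_defs, build = dataset$build)
  attr(out, "stratum_levels") <- levels_out
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Stratified genetic-model association
#'
#' Stratifies the cases by a clinical rule and delegates to [run_models()]
#' with the strata as columns in the rule's declared order (for binary
#' rules: negative = column 1, positive = column 2, so the default `col2`
#' OR orientation reproduces the published stratified tables).  For an
#' ordinal rule with more than two levels, the reference level is compared
#' pairwise against each other level and a list of results is returned.
#'
#' @param dataset A [genotype_dataset()] containing cases (and possibly
#'   controls, which are excluded).
#' @param snp_id rsID to analyse.
#' @param rule A [stratum_rule()].
#' @param outcome OR orientation, see [odds_ratio()].
#' @param case_group Label of the case group.
#' @return A `model_results` object (or a named list of them for > 2
#'   strata).
#' @export
run_stratified <- function(dataset, snp_id, rule,
                           outcome = c("col2", "col1"),
                           case_group = "case") {
  outcome <- match.arg(outcome)
  strat <- stratify(dataset, rule, case_group = case_group)
  lv <- attr(strat, "stratum_levels")
  if (length(lv) == 2L)
    return(run_models(strat, snp_id, group_pair = lv, outcome = outcome))
  res <- lapply(lv[-1], function(l)
    run_models(strat, snp_id, group_pair = c(lv[1], l), outcome = outcome))
  setNames(res, paste(lv[1], "vs", lv[-1]))
}

#' Render an association block as a published-style text table
#'
#' Codominant rows first, then one block per collapsed model; ORs and CIs
#' are rounded half-up to 2 decimals, reference rows print `"1.00"`, and the
#' model's likelihood-ratio p-value sits on its first row.  Rendering is
#' deterministic: the same input yields byte-identical text.
#'
#' @param results A `model_results` object from [run_models()].
#' @param p_digits Decimals for p-values (default 3).
#' @return Character vector of lines (class `report_table`), one per table
#'   row, with a header and title.
#' @export
render_table <- function(results, p_digits = 3) {
  stopifnot(inherits(results, "model_results"))
  fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
  fmtp <- function(p) sub("0+$", "", sprintf(paste0("%.", p_digits, "f"), p))
  lines <- c(sprintf("%s\t%s (n = %d)\t%s (n = %d)\tOR (95%%)\tp-Value",
                     results$snp$snp_id,
                     results$groups[1], sum(results$counts$counts[1, ]),
                     results$groups[2], sum(results$counts$counts[2, ])))
  res <- results$results
  for (mod in unique(res$model)) {
    block <- res[res$model == mod, , drop = FALSE]
    if (mod != "codominant") lines <- c(lines, paste0(toupper(substr(mod, 1, 1)),
                                                      substr(mod, 2, nchar(mod))))
    # reference row: counts are the model's reference-class counts
    ref_tab <- build_model_table(results$counts, mod)
    lines <- c(lines, sprintf("%s\t%d\t%d\t1.00\t%s",
                              rownames(ref_tab)[1], ref_tab[1, 1],
                              ref_tab[1, 2], fmtp(block$p_lr[1])))
    for (i in seq_len(nrow(block))) {
      or_cell <- if (is.na(block$or[i])) "NA" else
        sprintf("%s (%s-%s)", fmt2(block$or[i]), fmt2(block$ci_lo[i]),
                fmt2(block$ci_hi[i]))
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t", block$exposure[i],
                                block$n_1[i], block$n_2[i], or_cell))
    }
  }
  structure(lines, class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
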