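#' A GWAS-catalog association record
#'
#' @param snp_id rsID.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param trait Reported trait string.
#' @param reported_or Reported odds ratio (> 0).
#' @param maf Risk/minor allele frequency in (0, 0.5] reported by the
#'   catalog... values in (0, 1) are accepted, the selection filter applies
#'   to whatever is recorded.
#' @param ci_lo,ci_hi Optional confidence bounds; must bracket `reported_or`.
#' @param build Genome build metadata.
#' @return Object of class `gwas_record`.
#' @export
gwas_record <- function(snp_id, chrom, pos, trait = "", reported_or, maf,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        build = NA_character_) {
  stopifnot(nzchar(snp_id), reported_or > 0, maf > 0, maf < 1)
  if (!is.na(ci_lo) && !is.na(ci_hi) &&
      !(ci_lo <= reported_or && reported_or <= ci_hi))
    stop("confidence interval must bracket the reported OR for ", snp_id)
  structure(list(snp_id = snp_id, chrom = as.character(chrom),
                 pos = as.numeric(pos), trait = trait,
                 reported_or = reported_or, maf = maf,
                 ci_lo = ci_lo, ci_hi = ci_hi, build = build),
            class = "gwas_record")
}

#' A genomic interval hosting an lncRNA
#'
#' Intervals are 0-based half-open (`[start, end)`), the BED convention.
#' Strand is recorded but ignored for SNP overlap, which is positional only.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param name lncRNA symbol (may be `""`).
#' @param strand `"+"`, `"-"` or `"*"` (unknown).
#' @param build Genome build metadata.
#' @return Object of class `lnc_interval`.
#' @export
lnc_interval <- function(chrom, start, end, name = "", strand = "*",
                         build = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end,
         ")")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 name = name, strand = strand, build = build),
            class = "lnc_interval")
}

#' Read a delimited genotype table
#'
#' Expects a header row with `sample_id`, `group`, one column per SNP named
#' by rsID holding two-character genotype strings (e.g. `"CT"`; allele order
#' irrelevant), and optionally further clinical columns.  Genotypes are
#' normalized to alphabetically sorted allele pairs; alleles not belonging to
#' the SNP's definition raise a validation error naming SNP and sample;
#' malformed rows raise a parse error with the line number.
#'
#' @param path File path.
#' @param snp_defs List of [snp_def()]s; their ids select the SNP columns.
#' @param sep Field separator (default `","`).
#' @param missing_token String(s) denoting a missing genotype.
#' @param build Genome build metadata for the dataset.
#' @return A [genotype_dataset()]; per-SNP missing counts are available via
#'   [missing_counts()].
#' @export
read_genotype_table <- function(path, snp_defs, sep = ",",
                                missing_token = c("", "--", "NN", "00"),
                                build = NA_character_) {
  raw <- tryCatch(
    read.table(path, header = TRUE, sep = sep, colClasses = "character",
               check.names = FALSE, na.strings = NULL, fill = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  ids <- vapply(snp_defs, `[[`, "", "snp_id")
  need <- c("sample_id", "group", ids)
  if (!all(need %in% names(raw)))
    stop("missing column(s): ", paste(setdiff(need, names(raw)),
                                      collapse = ", "))
  samples <- raw[, setdiff(names(raw), ids), drop = FALSE]
  gmat <- as.matrix(raw[, ids, drop = FALSE])
  gmat[gmat %in% missing_token] <- NA_character_
  rownames(gmat) <- samples$sample_id
  genotype_dataset(samples, gmat, snp_defs, build = build)
}

#' Write a genotype dataset back to a delimited table
#'
#' Inverse of [read_genotype_table()]: writing then reading reproduces the
#' normalized genotypes and missingness exactly.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path.
#' @param sep Field separator.
#' @param missing_token String written for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(dataset, path, sep = ",",
                                 missing_token = "--") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$genotypes
  g[is.na(g)] <- missing_token
  out <- cbind(dataset$samples, as.data.frame(g, stringsAsFactors = FALSE))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields of biallelic records; phase separators are ignored
#' (`|` is treated as `/`), half-missing calls become missing, and
#' multi-allelic records are skipped with a warning.
#'
#' @param path VCF path (plain or bgzipped).
#' @param sample_group_map Named character vector mapping every VCF sample
#'   name to a group label; a VCF sample absent from the map is an error.
#' @param build Genome build metadata.
#' @return A [genotype_dataset()].  Major/minor allele assignment follows
#'   REF/ALT; [count_genotypes()] re-orients by pooled frequency downstream.
#' @export
read_vcf_genotypes <- function(path, sample_group_map,
                               build = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  vcf_samples <- colnames(gt)
  missing_map <- setdiff(vcf_samples, names(sample_group_map))
  if (length(missing_map))
    stop("sample(s) absent from group map: ",
         paste(missing_map, collapse = ", "))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) | !nzchar(fix[, "ALT"])
  if (any(multi)) {
    warning("skipping ", sum(multi), " multi-allelic or ALT-less record(s)")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no usable biallelic records in ", path)
  snp_defs <- lapply(seq_len(nrow(fix)), function(i) {
    id <- fix[i, "ID"]
    if (is.na(id) || id == ".") id <- paste0(fix[i, "CHROM"], ":",
                                             fix[i, "POS"])
    snp_def(id, fix[i, "CHROM"], as.numeric(fix[i, "POS"]),
            major_allele = fix[i, "REF"], minor_allele = fix[i, "ALT"],
            build = build)
  })
  gmat <- matrix(NA_character_, length(vcf_samples), nrow(fix))
  for (i in seq_len(nrow(fix))) {
    al <- c(fix[i, "REF"], fix[i, "ALT"])
    calls <- gsub("\\|", "/", gt[i, ])
    parts <- strsplit(calls, "/", fixed = TRUE)
    gmat[, i] <- vapply(parts, function(p) {
      if (length(p) != 2L || any(p == ".") || any(is.na(p)))
        return(NA_character_)   # half-missing or missing call
      paste0(al[as.integer(p[1]) + 1L], al[as.integer(p[2]) + 1L])
    }, "")
  }
  colnames(gmat) <- vapply(snp_defs, `[[`, "", "snp_id")
  samples <- data.frame(sample_id = vcf_samples,
                        group = unname(sample_group_map[vcf_samples]),
                        stringsAsFactors = FALSE)
  genotype_dataset(samples, gmat, snp_defs, build = build)
}

#' Read a GWAS-catalog-style association TSV
#'
#' Reads the tab-separated export format of the GWAS catalog (columns
#' `SNPS`, `CHR_ID`, `CHR_POS`, `OR or BETA`, `RISK ALLELE FREQUENCY`,
#' `DISEASE/TRAIT`; configurable via `columns`).  Rows whose position or
#' frequency does not parse are dropped, with the dropped count reported in
#' attribute `n_dropped` and a message.
#'
#' @param path TSV path.
#' @param columns Named character vector mapping the internal field names
#'   `snp`, `chrom`, `pos`, `or`, `maf`, `trait` to header names in the file.
#' @param build Genome build metadata attached to each record.
#' @return List of [gwas_record()]s with attribute `n_dropped`.
#' @export
read_gwas_catalog <- function(path,
                              columns = c(snp = "SNPS", chrom = "CHR_ID",
                                          pos = "CHR_POS", or = "OR or BETA",
                                          maf = "RISK ALLELE FREQUENCY",
                                          trait = "DISEASE/TRAIT"),
                              build = NA_character_) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols))
    stop("GWAS table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  pos <- suppressWarnings(as.numeric(raw[[columns[["pos"]]]]))
  orv <- suppressWarnings(as.numeric(raw[[columns[["or"]]]]))
  maf <- suppressWarnings(as.numeric(raw[[columns[["maf"]]]]))
  ok <- is.finite(pos) & pos >= 1 & is.finite(orv) & orv > 0 &
    is.finite(maf) & maf > 0 & maf < 1 & nzchar(raw[[columns[["snp"]]]])
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("read_gwas_catalog: dropped ", n_dropped,
            " unparseable row(s) of ", nrow(raw))
  records <- lapply(which(ok), function(i) {
    gwas_record(snp_id = raw[[columns[["snp"]]]][i],
                chrom = raw[[columns[["chrom"]]]][i], pos = pos[i],
                trait = raw[[columns[["trait"]]]][i],
                reported_or = orv[i], maf = maf[i], build = build)
  })
  attr(records, "n_dropped") <- n_dropped
  records
}

#' Read lncRNA intervals from a BED3/BED4 file
#'
#' BED coordinates are 0-based half-open and kept that way internally.
#' Column 4, when present, supplies the lncRNA name; column 6 the strand.
#' A line with `start >= end` or a negative start is a validation error
#' reporting the line number.
#'
#' @param path BED path.
#' @param build Genome build metadata attached to each interval.
#' @return List of [lnc_interval()]s.
#' @export
read_lncrna_bed <- function(path, build = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) &
                 !grepl("^(track|browser|#)", lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 3L)
      stop("BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end)
      stop("BED line ", i, ": invalid interval [", f[2], ", ", f[3], ")")
    lnc_interval(f[1], start, end,
                 name = if (length(f) >= 4L) f[4] else "",
                 strand = if (length(f) >= 6L && f[6] %in% c("+", "-"))
                   f[6] else "*",
                 build = build)
  })
}

#' Write analysis results to TSV
#'
#' Writes any of the package's result data frames (or a [run_models()]
#' result's `$results`) with deterministic column order, full-precision
#' numeric columns, and additional display-rounded columns (`*_display`,
#' round-half-up to 2 decimals) for OR and CI fields, matching the
#' conventions of published association tables.
#'
#' @param results `data.frame` (or `model_results`, from which `$results` is
#'   taken).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  if (inherits(results, "model_results")) results <- results$results
  results <- as.data.frame(results)
  for (col in intersect(c("or", "ci_lo", "ci_hi"), names(results))) {
    results[[paste0(col, "_display")]] <-
      sprintf("%.2f", round_half_up(results[[col]], 2))
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  write.table(format(results, digits = 15, trim = TRUE, nsmall = 0,
                     scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
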