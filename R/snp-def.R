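#' Define a biallelic SNP
#'
#' A `snp_def` records the identity of one biallelic single nucleotide
#' polymorphism: its rsID, genomic location, major/minor alleles and,
#' optionally, the lncRNA gene hosting it.  Every genotype container in the
#' package carries a list of `snp_def`s, and genotype validation is performed
#' against their alleles.
#'
#' @param snp_id rsID string, non-empty.
#' @param chrom Chromosome name (e.g. `"chr16"` or `"16"`).
#' @param pos 1-based genomic position, `>= 1`.
#' @param major_allele,minor_allele Single bases; must differ.
#' @param host_gene Symbol of the lncRNA containing the SNP, or `""`.
#' @param build Genome build label carried as metadata (e.g. `"GRCh37"`).
#'   Interval/SNP overlap refuses to mix builds rather than lift over.
#'
#' @return An object of class `snp_def`.
#' @examples
#' snp_def("rs4784227", "chr16", 52599188, "C", "T", host_gene = "CASC16")
#' @export
snp_def <- function(snp_id, chrom, pos, major_allele, minor_allele,
                    host_gene = "", build = NA_character_) {
  stopifnot(is.character(snp_id), length(snp_id) == 1L, nzchar(snp_id))
  pos <- as.numeric(pos)
  if (!is.finite(pos) || pos < 1)
    stop("'pos' must be a 1-based position >= 1 for ", snp_id)
  major_allele <- toupper(major_allele)
  minor_allele <- toupper(minor_allele)
  for (a in c(major_allele, minor_allele))
    if (!grepl("^[ACGT]$", a))
      stop("allele must be a single base (ACGT), got '", a, "' for ", snp_id)
  if (major_allele == minor_allele)
    stop("major and minor allele must differ for ", snp_id)
  structure(
    list(snp_id = snp_id, chrom = as.character(chrom), pos = pos,
         major_allele = major_allele, minor_allele = minor_allele,
         host_gene = host_gene, build = build),
    class = "snp_def")
}

#' @export
print.snp_def <- function(x, ...) {
  cat(sprintf("<snp_def> %s %s:%d %s>%s%s\n", x$snp_id, x$chrom, x$pos,
              x$major_allele, x$minor_allele,
              if (nzchar(x$host_gene)) paste0(" [", x$host_gene, "]") else ""))
  invisible(x)
}

#' Normalize unphased genotype strings
#'
#' Genotypes are stored as two-character strings with alleles in alphabetical
#' order, so `"TC"` and `"CT"` denote the same unordered pair.  Missing
#' genotypes are `NA`.  Normalization is idempotent and order-insensitive.
#'
#' @param g Character vector of two-character genotype strings (or `NA`).
#' @param missing_token Additional string(s) treated as missing.
#' @return Character vector of sorted-allele genotypes with `NA` for missing.
#' @examples
#' normalize_genotype(c("TC", "CT", NA, "GG"))
#' @export
normalize_genotype <- function(g, missing_token = c("", "--", "NN", "00")) {
  g <- as.character(g)
  g[g %in% missing_token | is.na(g)] <- NA_character_
  ok <- !is.na(g)
  if (any(nchar(g[ok]) != 2L))
    stop("genotypes must be two-character strings, got: ",
         paste(unique(g[ok][nchar(g[ok]) != 2L]), collapse = ", "))
  gg <- toupper(g[ok])
  a1 <- substr(gg, 1, 1); a2 <- substr(gg, 2, 2)
  g[ok] <- ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
  g
}

# the three genotype classes of a snp_def, alphabetically normalized
genotype_classes <- function(snp) {
  het <- paste(sort(c(snp$major_allele, snp$minor_allele)), collapse = "")
  c(hom_major = paste0(snp$major_allele, snp$major_allele),
    het = het,
    hom_minor = paste0(snp$minor_allele, snp$minor_allele))
}
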