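---
title: "Methods: lncRNA-SNP selection and case-control association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA-SNP selection and case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsnp)
```

## Scope and data model

`lncsnp` implements a complete workflow for studying single nucleotide
polymorphisms (SNPs) hosted in long noncoding RNA (lncRNA) genes in a
case-control design: candidate selection from differential-expression and
GWAS-catalog evidence, Hardy-Weinberg testing, genetic-model odds ratios,
EM haplotype estimation with linkage-disequilibrium statistics, and
clinically stratified re-analysis.

The central container is the `genotype_dataset`: a sample table (id, group,
clinical covariates), an unphased genotype matrix of normalized
two-character allele strings (`"CT"` and `"TC"` are the same unordered
pair), and a list of `snp_def`s.  All analyses are **complete-case per
SNP** — each SNP is analyzed on its non-missing samples — which is why the
bundled cohort's per-SNP totals (254–285 cases) differ from the 291
enrolled patients.  Genome build is carried as metadata on SNPs and
intervals, and mixing builds is an error rather than a silent liftover,
because coordinate provenance in public catalogs is a common silent
failure.

## Candidate selection

Selection is a conjunction of three filters with set-intersection
semantics (order-commutative, idempotent), followed by a ranking:

1. **Tumor-vs-normal differential expression.** `log2fc` is the difference
   of group means of `log2(x + 1)`; the p-value comes from Welch's
   unequal-variance t-test on the same transformed values.  The default
   thresholds are a *linear* fold change above 1.5 — i.e.
   `|log2fc| > log2(1.5) ≈ 0.585` — and `p < 0.001` with no
   multiple-testing correction.  The linear reading matters: bundled
   candidates with `log2fc` 0.87 or −0.69 pass the filter, which they
   would not under a log2-scale reading.  The location test itself is
   isolated behind `compute_de()` so a count-based DE engine could be
   swapped in; only monotone separation is required of it here.
2. **GWAS/interval intersection with a MAF filter.** A SNP (1-based
   catalog position, converted to a 0-based point) is paired with every
   lncRNA interval (BED convention, 0-based half-open) containing it;
   a SNP exactly at an interval's end coordinate is outside.  Overlap is
   purely positional — strand is read but ignored.  Records then must have
   minor allele frequency **strictly** above 0.20 ("higher than" is read
   as a strict inequality, so MAF = 0.20 is excluded as rare).
3. **Subtype differential expression.** The host lncRNA must be
   differentially expressed in at least one molecular subtype
   (subtype-vs-rest contrasts with the same test and thresholds).

`rank_select()` sorts surviving rows by reported OR descending and takes
rows until `n_select` distinct SNPs are collected; one row may carry two
SNPs (two variants tagging the same lncRNA).  Ties are broken by rsID
lexicographic order and flagged.

## Association engine

For one SNP and two groups, `count_genotypes()` produces the 2×3 genotype
count table, re-orienting major/minor by pooled frequency by default.
Four inheritance models collapse it: codominant (three genotypes,
hom-major reference), dominant (carriers vs hom-major), recessive
(hom-minor vs rest — the exposure is always the minor homozygote), and
overdominant (heterozygotes vs both homozygotes).

**Odds-ratio orientation.** With reference row `(a1, a2)` and exposure row
`(b1, b2)` over column groups 1 and 2, the default `outcome = "col2"`
computes `OR = (b2·a1)/(b1·a2)`, i.e. membership of the column-2 group is
the outcome.  This single convention reproduces every bundled published
table cell — for the case/control tables (controls in column 2) and the
case-only stratified tables (positive stratum in column 2) alike.  The
standard epidemiological orientation is its reciprocal
(`outcome = "col1"`).  The package reports the convention on every result
rather than silently "fixing" it, since the published verbal risk
interpretations correspond to the reciprocal reading.

The 95% CI is Wald on the log scale, `exp(log OR ± 1.96·√Σ 1/cell)`.  A
single zero cell triggers the Haldane–Anscombe correction (+0.5 to all
four cells, flagged); a zero margin leaves the OR undefined.

**Association test.** The primary p-value is the likelihood-ratio (G)
test, `G = 2 Σ obs·ln(obs/exp)` with independence expected counts and
`df = rows − 1`; the Pearson statistic is co-reported.  The choice is
empirical: the G-test reproduces the bundled tables' printed p-values
(0.022, 0.065, 0.015, 0.041, 0.048, 0.047) to within 0.001, while
Pearson deviates visibly on the small recessive cells, and any continuity
correction contradicts all of them.  Zero observed cells contribute 0
(the `x log x` limit).  No multiple-testing adjustment is applied, to
match the source analysis; the number of model tests run is recorded on
the result for a user who wants to adjust.

**HWE.** Per group, expected counts `n(p², 2pq, q²)` from that group's own
allele frequency and a 1-df chi-square.  Monomorphic SNPs return a
degenerate-but-defined result (chi² = 0, flagged).  All eight group×SNP
combinations of the bundled cohort are in HWE at α = 0.05 (minimum
p ≈ 0.093).

## Haplotypes and LD

`em_haplotypes()` estimates the four two-locus haplotype frequencies from
unphased genotypes by EM over the nine genotype classes.  Only double
heterozygotes are phase-ambiguous; the E-step splits them between the cis
and trans resolutions in proportion to current frequency products, the
M-step renormalizes expected haplotype counts.  Numerical choices:
initialization at linkage-equilibrium products of observed allele
frequencies (which makes the fully symmetric double-het-only case
deterministic — the estimate stays at the symmetric point and is
flagged); convergence when the largest frequency change is below 1e-8,
capped at 1000 iterations (a four-parameter problem, typically <20
iterations); the log-likelihood trace is returned and is non-decreasing
by construction of EM, which the test suite asserts on every run.  With
no double heterozygotes the first M-step is exact direct counting.

`ld_from_haplotypes()` evaluates `D = f11 − pA·pB`, `D' = D/Dmax`
(`Dmax = min(pA·qB, qA·pB)` for positive D, mirrored for negative), and
`r² = D²/(pA·qA·pB·qB)`; `r² ≤ D'²` is property-tested on random simplex
draws.

`haplotype_association()` converts per-group frequencies to estimated
counts (`2N·freq`, rounded, flagged as estimated rather than observed)
and tests each haplotype against the most frequent pooled haplotype with
the same OR/G-test machinery.  The source cohort's joint two-SNP genotype
table was never published, so the haplotype stage is validated by
parameter recovery on synthetic data rather than by golden-table
reproduction; whether the original analysis used estimated-count tables
or a score test is unknowable, and the estimated-count choice is
documented here as this package's own.

## Clinical stratification

`stratify()` partitions *cases only* (controls never enter a stratified
run): numeric covariates are dichotomized at a cutoff — values exactly at
the cutoff go to the "higher" stratum, a convention this package fixes
because the source left it unstated (the bundled cutoff 57.90 is the
cohort's mean age at diagnosis) — binary statuses use declared
(negative, positive) order so that the default OR orientation reproduces
the published stratified tables, and ordinal covariates (tumor grade
I/II/III) are analyzed as pairwise contrasts against the first level,
since no published grade table exists to match.  Missing clinical values
are dropped with a logged count, and stratum sizes plus dropped always
partition the case total.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions the package is validated
under:

- `gen_cohort()` draws genotypes i.i.d. per sample, either from HWE
  proportions at a given MAF or from explicit per-group genotype
  probabilities.  Effects are deliberately specified as per-group
  genotype probabilities rather than through a logistic model: every
  quantity the engine estimates is a genotype-count contrast, so this
  makes expected ORs analytic and exact oracles available.
  `default_cohort_spec()` is the bundled cohort itself: 291 cases / 370
  controls, empirical genotype fractions, and per-SNP per-group
  missingness backed out of the published per-SNP totals.
- `gen_two_locus()` draws two haplotypes i.i.d. per individual and
  exposes only unphased genotypes, keeping the true phase in an audit
  attribute so tests can compare EM output against a phase-known oracle.
- `gen_expression()` draws `2^(baseline + planted log2FC + N(0, σ))`;
  baselines default to Unif(1, 8) on the log2 scale and σ = 1 by default
  (σ = 0.3 in the DE fixtures), chosen as a realistic FPKM-like spread.
  It emulates monotone group separation only — no count overdispersion,
  gene-gene correlation, or library-size effects — which is sufficient
  because the DE filter is a location test on log values.
- One integer seed drives everything, split with fixed offsets per
  generator, so adding a generator never shifts existing streams.

Passing recovery tests on these generators shows the estimators are
correct under clean sampling assumptions (binomial/multinomial noise,
independent samples); it does not certify behavior under population
structure, genotyping batch effects, or LD beyond two loci, none of which
are simulated.

A note on the bundled haplotype frequency vector: the published column
(0.67, 0.25, 0.0735, 0.0081) sums to 1.0016, so
`cohort_haplotype_frequencies()` normalizes by the sum (default) before it
is used as a simulation truth.

## Problem sizes and reproducibility

Validation uses 10⁴ individuals for haplotype-frequency recovery
(binomial SE ≈ 0.003 per frequency, against a ±0.01 tolerance), 10⁴ per
group for the planted haplotype OR, and 10⁵ per group for genotype-model
OR recovery (2-SE log-scale tolerance ≈ 0.02) — sizes at which
Monte-Carlo error is comfortably below the assertion tolerances while an
entire validation run stays in the seconds range.  `scripts/acceptance.R`
re-derives every headline number from scratch at these sizes under a
user-supplied seed.

## Known limitations

- Biallelic SNPs only; multi-allelic VCF records are skipped with a
  warning, and there is no imputation or liftover.
- No covariate-adjusted (logistic) models and no exact (Fisher) tests;
  association inference is the G test with Wald intervals, which is
  accurate at the bundled cohort's cell sizes but approximate for very
  sparse tables even after the Haldane correction.
- Haplotype association treats estimated counts as observed, ignoring EM
  uncertainty; with the near-complete LD and sample sizes involved the
  effect is small, but CIs for very rare haplotypes should be read
  cautiously.
- The DE stage is a two-group location test on transformed abundances,
  not a count-model DE method; it is a filter, not an inferential claim
  about expression.
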