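# lncsnp

Case-control genetics of SNPs hosted in long noncoding RNAs (lncRNAs).

Most breast-cancer risk variants found by GWAS sit in noncoding DNA, and a
growing share of them fall inside lncRNA genes, where an allele can change a
regulatory transcript's structure or expression rather than a protein. This
package is for researchers running candidate lncRNA-SNP studies in their own
cohorts: it selects candidate SNPs by intersecting differential-expression
evidence with GWAS-catalog associations, then performs the full
genotype-level analysis of a case-control study — Hardy-Weinberg testing,
genetic-model odds ratios, haplotype estimation, linkage disequilibrium, and
clinical stratification. Genotype counts from a published Brazilian
breast-cancer cohort (four SNPs: rs3803662, rs4415084, rs4784227, rs7716600)
are bundled as golden reference tables, and a synthetic-cohort generator with
analytic ground truth makes every stage testable without external downloads.

## The statistics at the core

For one biallelic SNP with genotype counts $(n_{AA}, n_{Aa}, n_{aa})$ per
group:

- **Hardy-Weinberg equilibrium** per group: expected counts
  $n(p^2, 2pq, q^2)$ from that group's allele frequency $p$, tested with a
  1-df $\chi^2$.
- **Genetic models** collapse the 2×3 table: codominant (each genotype vs
  hom-major), dominant ($Aa{+}aa$ vs $AA$), recessive ($aa$ vs rest),
  overdominant ($Aa$ vs both homozygotes).
- **Odds ratio** with reference row $(a_1, a_2)$ and exposure row
  $(b_1, b_2)$ over the two group columns:
  $\mathrm{OR} = (b_2 a_1)/(b_1 a_2)$ under the default column-2-as-outcome
  orientation (the convention of the bundled published tables; the standard
  epidemiological orientation is the reciprocal, via `outcome = "col1"`).
  95% Wald CI: $\exp(\ln \mathrm{OR} \pm 1.96\sqrt{\sum 1/\text{cell}})$,
  with Haldane-Anscombe correction for single zero cells.
- **Association p-value**: likelihood-ratio $G = 2\sum o \ln(o/e)$ against
  independence margins (Pearson $X^2$ co-reported, no continuity
  correction).
- **Haplotypes**: EM over the nine unphased two-locus genotype classes
  (only double heterozygotes are phase-ambiguous), then
  $D = f_{11} - p_A p_B$, $D' = D/D_{\max}$,
  $r^2 = D^2/(p_A q_A p_B q_B)$, and per-haplotype odds ratios against the
  most frequent haplotype.

Candidate selection applies three filters — linear fold change $>1.5$ with
$p < 0.001$ tumor-vs-normal, SNP position inside an lncRNA interval with
MAF strictly $> 0.20$, and differential expression in at least one molecular
subtype — then ranks surviving SNPs by reported OR.

## Worked example

Genetic-model analysis of rs4415084 from the bundled cohort counts:

```r
library(lncsnp)
counts <- cohort_genotype_counts()[["rs4415084"]]
run_models(counts)
#> rs4415084  case (n = 285)  control (n = 357)  OR (95%)  p-Value
#> CC      104  100  1.00  0.065
#> CT      132  182  1.43 (1.01-2.04)
#> TT      49   75   1.59 (1.01-2.50)
#> Dominant
#> CC      104  100  1.00  0.022
#> CT/TT   181  257  1.48 (1.06-2.06)
#> Recessive
#> CC/CT   236  282  1.00  0.222
#> TT      49   75   1.28 (0.86-1.91)
#> Overdominant
#> CC/TT   153  175  1.00  0.24
#> CT      132  182  1.21 (0.88-1.65)
```

The dominant model is the significant one: carrying at least one T allele
has OR 1.48 (95% CI 1.06–2.06, G-test p = 0.022) under the
column-2-as-outcome orientation. Both groups are in Hardy-Weinberg
equilibrium, and the pooled T-allele frequency is 0.44:

```r
hwe_test(counts, "control")
#> HWE [control]: chi2 = 0.2166 (df = 1), p = 0.6416
allele_frequency(counts, "T")
#>     group allele      freq
#> 1    case      T 0.4035088
#> 2 control      T 0.4649860
#> 3  pooled      T 0.4376947
```

A synthetic two-locus cohort drawn from the bundled rs3803662/rs4784227
haplotype frequencies, re-estimated by EM:

```r
defs <- cohort_snp_defs()
spec <- two_locus_spec(unname(cohort_haplotype_frequencies()),
                       c(case = 5000, control = 5000),
                       defs[["rs3803662"]], defs[["rs4784227"]], seed = 11)
em_haplotypes(gen_two_locus(spec), "rs3803662", "rs4784227")
#> <haplotype_estimate> rs3803662/rs4784227, n = 10000, converged in 9 iterations
#>     GC     GT     AC     AT
#> 0.6739 0.0085 0.0712 0.2464
```

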