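# hapase — haplotype-aware allele-specific expression analysis

In a diploid genome the two alleles of an autosomal gene are usually
expressed equally; a reproducible imbalance — allele-specific expression
(ASE) — is a fingerprint of cis-regulatory or epigenetic variation. hapase
is an R package for detecting ASE the haplotype-aware way: heterozygous
SNPs phased into per-gene haplotypes (e.g. from full-length Iso-seq
transcripts, carried as a phased VCF) are combined with short-read RNA-seq
pileups, nucleotide tallies at each locus are summed per haplotype, and
allelic imbalance is tested per event. It was built around a multi-tissue
equine FAANG study design — phased events across nine tissues, histone-mark
ChIP-seq context, and replication in a 66-sample liver cohort — but every
stage is generic.

The statistic is the allele expression fold change over haplotype-summed
read counts,

```
aeFC = log2(allele1_exp) − log2(allele2_exp)
```

with an exact two-sided binomial test of `allele1_exp` against
`Binom(allele1_exp + allele2_exp, 0.5)` and Benjamini–Hochberg FDR control
within each (tissue, sample) dataset. An event is significant iff
`|aeFC| ≥ 2`, adjusted `p ≤ 0.05`, and at least one allele has ≥ 5 reads;
events where neither allele reaches 10 reads are never tested. Downstream,
each event is placed in context: variant consequence classification against
transcript models (UTR / missense / synonymous / stop / splice-region /
non-coding, with intronic-or-intergenic-only loci excluded), overlap of the
event region with histone-mark peaks (H3K27ac, H3K4me1, H3K4me3, H3K27me3),
per-tissue summary tables, hypergeometric pathway over-representation, and
per-locus replication statistics in an independent cohort. A synthetic-data
generator with known ground truth (Poisson depth, binomial allele counts)
makes the whole pipeline testable end to end.

## Worked example

```r
library(hapase)

cfg <- sim_config(n_genes = 300, mean_depth = 80, ase_fraction = 0.1,
                  fold_change = 6, seed = 11)
res <- run_ase_pipeline(cfg, tissues = c("liver", "heart"),
                        validate_tissue = "liver")
res$tissue_summary
#>   tissue allele_comparisons ase_count  pct
#> 1  heart                284        24 8.45
#> 2  liver                284        24 8.45
#> 3    all                568        48 8.45
```

284 of the 300 simulated genes pass the autosome and ≥10-read filters in
each tissue; this draw contains 26 truly imbalanced genes, of which 24 sit
on autosomes — and all 24 are recovered in each tissue. The per-event table
shows the haplotype sums behind each call:

```r
head(res$events[res$events$significant,
     c("gene_id", "tissue", "allele1_exp", "allele2_exp", "aefc", "adj_p")], 4)
#>      gene_id tissue allele1_exp allele2_exp  aefc    adj_p
#> 22 gene00022  liver          64         429 -2.74 3.14e-65
#> 27 gene00028  liver          56         315 -2.49 1.77e-43
#> 31 gene00032  liver          24         135 -2.49 8.31e-19
#> 37 gene00038  liver          37         278 -2.91 2.16e-45
```

`gene00022` expresses haplotype 2 about 6.7-fold (`2^2.74`) above
haplotype 1. Re-testing the significant liver loci in a simulated 66-sample
cohort:

```r
res$validation$summary[c("n_comparisons", "pct_significant",
                         "pct_same_direction")]
#> 4707 comparisons, 92.31% significant, 100% same direction
```

File-based inputs enter through `read_phased_vcf()`, `read_mpileup()`,
`read_bed_peaks()`, `read_gtf()`; a thin command-line wrapper with
`simulate` / `count` / `test` / `annotate` / `overlap` / `validate`
subcommands lives at `inst/cli/hapase-cli.R`. The methods vignette
(`vignettes/haplotype-ase-methods.Rmd`) documents the model, conventions
and limitations.

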