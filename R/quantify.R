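# Nucleotide tallying at phased heterozygous loci and per-haplotype
# aggregation into event-level expression values.

#' Aggregate locus tallies into per-haplotype expression per event
#'
#' For every phased event (the loci sharing one `phase_set`), sums the reads
#' matching the haplotype-1 base over all loci into `allele1_exp`, the
#' haplotype-2 base into `allele2_exp`, and reads matching neither haplotype
#' base (including ambiguous `N`) into `other_exp`. Expression values are
#' raw integer read counts, never normalized. Loci missing from the counts
#' table contribute zero with a warning: short-read coverage is uneven and
#' low totals are handled by the downstream prefilter.
#'
#' @param loci Het-locus data.frame (see [read_phased_vcf()]).
#' @param counts Locus-counts data.frame (see [read_mpileup()]), indexed by
#'   `(chrom, pos)`.
#' @return A haplotype-expression data.frame with one row per event:
#'   `gene_id`, `phase_set`, `chrom`, `first_pos`, `last_pos`, `n_loci`,
#'   `allele1_exp`, `allele2_exp`, `other_exp`.
#' @export
tally_events <- function(loci, counts) {
  validate_het_loci(loci)
  if (nrow(loci) == 0L) stop("no loci to tally")
  key_l <- paste(loci$chrom, loci$pos)
  key_c <- paste(counts$chrom, counts$pos)
  idx <- match(key_l, key_c)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0L) {
    warning(n_missing, " phased locus/loci without pileup coverage ",
            "(counted as zero)")
  }
  base_mat <- as.matrix(counts[, ASE_BASES, drop = FALSE])
  get_base <- function(which_base) {
    v <- numeric(nrow(loci))
    ok <- !is.na(idx)
    v[ok] <- base_mat[cbind(idx[ok], match(which_base[ok], ASE_BASES))]
    v
  }
  a1 <- get_base(loci$hap1_base)
  a2 <- get_base(loci$hap2_base)
  tot <- numeric(nrow(loci))
  ok <- !is.na(idx)
  tot[ok] <- rowSums(base_mat[idx[ok], , drop = FALSE]) +
    if ("N" %in% names(counts)) counts$N[idx[ok]] else 0
  other <- tot - a1 - a2

  ps <- factor(loci$phase_set, levels = unique(loci$phase_set))
  out <- event_regions(loci)
  out$allele1_exp <- as.vector(tapply(a1, ps, sum))
  out$allele2_exp <- as.vector(tapply(a2, ps, sum))
  out$other_exp <- as.vector(tapply(other, ps, sum))
  out[, c("gene_id", "phase_set", "chrom", "first_pos", "last_pos",
          "n_loci", "allele1_exp", "allele2_exp", "other_exp")]
}

#' Remove events on sex chromosomes
#'
#' Splits a table with a `chrom` column into autosomal and sex-chromosome
#' records. Dropped records are not deleted: they are returned alongside the
#' kept ones and, if `side_path` is given, written to a side-channel TSV so
#' they stay available for analysis.
#'
#' @param x Data.frame with a `chrom` column (haplotype expression, events,
#'   or loci).
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @param side_path Optional TSV path for the dropped records.
#' @return A list with `kept` (autosomal rows) and `dropped` (sex-chromosome
#'   rows).
#' @export
drop_sex_chromosomes <- function(x, sex_chroms = c("chrX", "chrY", "X", "Y"),
                                 side_path = NULL) {
  on_sex <- x$chrom %in% sex_chroms
  dropped <- x[on_sex, , drop = FALSE]
  kept <- x[!on_sex, , drop = FALSE]
  rownames(kept) <- rownames(dropped) <- NULL
  if (!is.null(side_path)) write_tsv(dropped, side_path)
  list(kept = kept, dropped = dropped)
}
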