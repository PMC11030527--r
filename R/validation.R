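# Replication of discovery ASE loci in an independent multi-sample cohort:
# per-sample heterozygosity filtering, per-locus re-testing under the
# discovery significance criteria, and confirmation / direction-concordance
# summaries.

#' Re-test discovery loci in a multi-sample cohort
#'
#' For every sample-by-locus pair present in the cohort counts, extracts the
#' two discovery alleles' read counts (allele order matched to discovery by
#' base identity, so direction is comparable), drops pairs that are not
#' heterozygous under the het rule, and applies the discovery statistics:
#' aeFC, exact binomial p, BH within each sample, and significance iff
#' |aeFC| >= `fc_min` and adjusted p <= `alpha`. No extra count prefilter is
#' applied beyond the het rule. The default het rule calls a locus
#' heterozygous in a sample iff both discovery alleles have at least
#' `het_min_allele` reads and the combined allele depth is at least
#' `het_min_depth`; RNA-only heterozygosity calls are circular under strong
#' imbalance, so genotype-based pre-filtering of `cohort_counts` is the
#' cleaner path when genotypes exist.
#'
#' @param discovery_loci Het-locus data.frame of loci to re-test (`chrom`,
#'   `pos`, `hap1_base`, `hap2_base`, ...).
#' @param cohort_counts Per-sample locus counts: a data.frame with
#'   `sample_id`, `chrom`, `pos` and nucleotide tally columns `A`, `C`, `G`,
#'   `T` (see [sim_validation_cohort()] or [read_mpileup()] plus a
#'   `sample_id` column).
#' @param het_min_allele,het_min_depth Het-rule parameters.
#' @param fc_min,alpha Significance thresholds (|aeFC| and adjusted p).
#' @return A validation-record data.frame: `sample_id`, `chrom`, `pos`,
#'   `locus_id`, `allele1_count`, `allele2_count`, `aefc`, `p_value`,
#'   `adj_p`, `significant`, `direction` (sign of aeFC).
#' @export
validate_loci <- function(discovery_loci, cohort_counts, het_min_allele = 1,
                          het_min_depth = 10, fc_min = 2, alpha = 0.05) {
  if (nrow(discovery_loci) == 0L) stop("discovery loci must be nonempty")
  key_d <- paste(discovery_loci$chrom, discovery_loci$pos)
  key_c <- paste(cohort_counts$chrom, cohort_counts$pos)
  idx <- match(key_c, key_d)
  present <- !is.na(idx)
  cc <- cohort_counts[present, , drop = FALSE]
  dd <- discovery_loci[idx[present], , drop = FALSE]

  base_mat <- as.matrix(cc[, ASE_BASES, drop = FALSE])
  a1 <- base_mat[cbind(seq_len(nrow(cc)), match(dd$hap1_base, ASE_BASES))]
  a2 <- base_mat[cbind(seq_len(nrow(cc)), match(dd$hap2_base, ASE_BASES))]

  het <- a1 >= het_min_allele & a2 >= het_min_allele &
    (a1 + a2) >= het_min_depth
  rec <- data.frame(
    sample_id = cc$sample_id[het],
    chrom = cc$chrom[het], pos = cc$pos[het],
    locus_id = paste0(cc$chrom[het], ":", cc$pos[het]),
    allele1_count = a1[het], allele2_count = a2[het],
    stringsAsFactors = FALSE
  )
  rec$aefc <- aefc(rec$allele1_count, rec$allele2_count)
  rec$p_value <- binom_ase_p(rec$allele1_count, rec$allele2_count)
  rec$adj_p <- NA_real_
  for (s in unique(rec$sample_id)) {
    si <- which(rec$sample_id == s)
    rec$adj_p[si] <- bh_adjust(rec$p_value[si])
  }
  rec$significant <- !is.na(rec$aefc) & !is.nan(rec$aefc) &
    abs(rec$aefc) >= fc_min & !is.na(rec$adj_p) & rec$adj_p <= alpha
  rec$direction <- sign(rec$aefc)
  rec$direction[is.nan(rec$aefc)] <- 0
  rownames(rec) <- NULL
  rec
}

#' Summarize cohort validation of discovery loci
#'
#' Computes the confirmation rate (significant comparisons / all retained
#' comparisons), direction concordance with the discovery call among the
#' significant comparisons, and per-locus replication: for each locus the
#' fraction of tested samples in which it was significant, the number of
#' loci significant in at least one sample, and the number whose fraction
#' reaches `replication_threshold`.
#'
#' @param records Validation-record data.frame from [validate_loci()].
#' @param discovery_directions Data.frame with `locus_id` and `direction`
#'   (sign of the discovery aeFC per locus); may be `NULL`, in which case
#'   direction concordance is `NA`.
#' @param replication_threshold Per-locus replication fraction counted as
#'   strong replication (default 0.9).
#' @return A list with `n_comparisons`, `n_significant`, `pct_significant`,
#'   `n_same_direction`, `pct_same_direction` (among significant),
#'   `per_locus` (data.frame `locus_id`, `n_samples_tested`,
#'   `n_samples_significant`, `replication_fraction`),
#'   `n_loci_tested`, `n_loci_replicated_any`, `pct_loci_replicated_any`,
#'   `n_loci_replicated_strong`, `pct_loci_replicated_strong`.
#' @export
summarize_validation <- function(records, discovery_directions = NULL,
                                 replication_threshold = 0.9) {
  n_comp <- nrow(records)
  if (n_comp == 0L) {
    return(list(
      n_comparisons = 0L, n_significant = 0L, pct_significant = 0,
      n_same_direction = 0L, pct_same_direction = NA_real_,
      per_locus = data.frame(locus_id = character(),
                             n_samples_tested = integer(),
                             n_samples_significant = integer(),
                             replication_fraction = numeric(),
                             stringsAsFactors = FALSE),
      n_loci_tested = 0L, n_loci_replicated_any = 0L,
      pct_loci_replicated_any = 0, n_loci_replicated_strong = 0L,
      pct_loci_replicated_strong = 0
    ))
  }
  n_sig <- sum(records$significant)
  sig <- records[records$significant, , drop = FALSE]
  if (!is.null(discovery_directions)) {
    disc <- discovery_directions$direction[
      match(sig$locus_id, discovery_directions$locus_id)]
    n_same <- sum(!is.na(disc) & sig$direction == disc)
    pct_same <- if (n_sig > 0L) round(100 * n_same / n_sig, 2) else NA_real_
  } else {
    n_same <- NA_integer_; pct_same <- NA_real_
  }

  loci <- unique(records$locus_id)
  tested <- vapply(loci, function(l) sum(records$locus_id == l), integer(1))
  sig_n <- vapply(loci, function(l) {
    sum(records$locus_id == l & records$significant)
  }, integer(1))
  per_locus <- data.frame(
    locus_id = loci, n_samples_tested = tested,
    n_samples_significant = sig_n,
    replication_fraction = sig_n / tested,
    stringsAsFactors = FALSE
  )
  rownames(per_locus) <- NULL
  n_loci <- nrow(per_locus)
  n_any <- sum(per_locus$n_samples_significant >= 1L)
  n_strong <- sum(per_locus$replication_fraction >= replication_threshold)
  list(
    n_comparisons = n_comp,
    n_significant = n_sig,
    pct_significant = round(100 * n_sig / n_comp, 2),
    n_same_direction = n_same,
    pct_same_direction = pct_same,
    per_locus = per_locus,
    n_loci_tested = n_loci,
    n_loci_replicated_any = n_any,
    pct_loci_replicated_any = round(100 * n_any / n_loci, 2),
    n_loci_replicated_strong = n_strong,
    pct_loci_replicated_strong = round(100 * n_strong / n_loci, 2)
  )
}
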