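test_that("identical config and seed reproduce the simulation exactly", {
  cfg <- sim_config(n_genes = 40, ase_fraction = 0.2, seed = 5)
  a <- sim_phased_loci(cfg)
  b <- sim_phased_loci(cfg)
  expect_identical(a, b)
  expect_identical(sim_locus_counts(a$loci, a$truth, cfg),
                   sim_locus_counts(b$loci, b$truth, cfg))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_ase_fixtures(d1, cfg)
  write_ase_fixtures(d2, cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("phased loci respect the structural contracts", {
  cfg <- sim_config(n_genes = 150, loci_per_gene = c(1, 5),
                    sex_chrom_fraction = 0.2, seed = 3)
  sim <- sim_phased_loci(cfg)
  expect_equal(nrow(sim$truth), 150)
  expect_true(all(sim$loci$hap1_base != sim$loci$hap2_base))
  # strictly increasing positions within every phase set
  by_ps <- split(sim$loci$pos, sim$loci$phase_set)
  expect_true(all(vapply(by_ps, function(p) all(diff(p) > 0), logical(1))))
  # every gene has at least one locus and appears exactly once in the truth
  expect_setequal(unique(sim$loci$gene_id), sim$truth$gene_id)
  expect_false(any(duplicated(sim$truth$gene_id)))
  # sex-chromosome genes appear at roughly the configured fraction
  frac_x <- mean(tapply(sim$loci$chrom, sim$loci$gene_id, `[`, 1) == "chrX")
  expect_gt(frac_x, 0.08)
  expect_lt(frac_x, 0.35)
  # null genes carry fold change 1
  expect_true(all(sim$truth$true_fold_change[!sim$truth$is_ase] == 1))
})

test_that("ase_fraction boundaries and the recorded fixed-seed draw hold", {
  cfg0 <- sim_config(n_genes = 60, ase_fraction = 0, seed = 8)
  expect_false(any(sim_phased_loci(cfg0)$truth$is_ase))
  # frozen fixture truth: this config draws 8 imbalanced genes
  cfg <- sim_config(n_genes = 100, ase_fraction = 0.1, seed = 2024)
  expect_identical(sum(sim_phased_loci(cfg)$truth$is_ase), 8L)
})

test_that("count model matches its Poisson-binomial definition", {
  # fold_change = 4 puts the favored-allele fraction at 4/5
  cfg <- sim_config(n_genes = 2000, loci_per_gene = 5, mean_depth = 60,
                    ase_fraction = 1, fold_change = 4, seed = 21)
  sim <- sim_phased_loci(cfg)
  counts <- sim_locus_counts(sim$loci, sim$truth, cfg)
  base_mat <- as.matrix(counts[, c("A", "C", "G", "T")])
  i <- seq_len(nrow(counts))
  a1 <- base_mat[cbind(i, match(sim$loci$hap1_base, c("A", "C", "G", "T")))]
  a2 <- base_mat[cbind(i, match(sim$loci$hap2_base, c("A", "C", "G", "T")))]
  expect_true(all(a1 + a2 == counts$depth))   # conservation, no error bases
  fav <- sim$truth$favored_haplotype[match(sim$loci$gene_id,
                                           sim$truth$gene_id)]
  fav_frac <- ifelse(fav == 1L, a1, a2) / pmax(1, counts$depth)
  expect_lt(abs(mean(fav_frac) - 0.8), 3 * 0.4 / sqrt(nrow(counts)))

  # null model: allele-1 fraction within 3 standard errors of 0.5
  cfg0 <- sim_config(n_genes = 2000, loci_per_gene = 5, mean_depth = 60,
                     ase_fraction = 0, seed = 22)
  sim0 <- sim_phased_loci(cfg0)
  c0 <- sim_locus_counts(sim0$loci, sim0$truth, cfg0)
  b0 <- as.matrix(c0[, c("A", "C", "G", "T")])
  a10 <- b0[cbind(seq_len(nrow(c0)),
                  match(sim0$loci$hap1_base, c("A", "C", "G", "T")))]
  f0 <- a10 / pmax(1, c0$depth)
  expect_lt(abs(mean(f0) - 0.5), 3 * 0.5 / sqrt(nrow(c0)))
})

test_that("degenerate depth and error-rate settings behave", {
  cfg <- sim_config(n_genes = 30, mean_depth = 0, seed = 2)
  sim <- sim_phased_loci(cfg)
  counts <- sim_locus_counts(sim$loci, sim$truth, cfg)
  expect_true(all(counts$depth == 0))
  ev <- ase_test(tally_events(sim$loci, counts))
  expect_false(any(ev$prefilter_pass))

  cfge <- sim_config(n_genes = 200, loci_per_gene = 2, mean_depth = 80,
                     error_rate = 0.1, seed = 4)
  sime <- sim_phased_loci(cfge)
  ce <- sim_locus_counts(sime$loci, sime$truth, cfge)
  expr <- tally_events(sime$loci, ce)
  expect_gt(sum(expr$other_exp), 0)   # errors land in the other tally
  bm <- as.matrix(ce[, c("A", "C", "G", "T")])
  expect_true(all(rowSums(bm) == ce$depth))   # conservation still exact
})

test_that("validation cohort respects het_rate boundaries and frozen draw", {
  cfg1 <- sim_config(n_genes = 10, loci_per_gene = 2, n_samples = 5,
                     het_rate = 1, seed = 6)
  sim <- sim_phased_loci(cfg1)
  coh <- sim_validation_cohort(sim$loci, sim$truth, cfg1)
  expect_equal(nrow(coh), 5 * nrow(sim$loci))

  cfg0 <- sim_config(n_genes = 10, loci_per_gene = 2, n_samples = 5,
                     het_rate = 0, seed = 6)
  coh0 <- sim_validation_cohort(sim$loci, sim$truth, cfg0)
  expect_equal(nrow(coh0), 0)

  # frozen fixture truth: 66 samples at het_rate 0.8 give 3,195 comparisons
  cfgv <- sim_config(n_genes = 30, loci_per_gene = 2, n_samples = 66,
                     het_rate = 0.8, seed = 99)
  simv <- sim_phased_loci(cfgv)
  cohv <- sim_validation_cohort(simv$loci, simv$truth, cfgv)
  rec <- validate_loci(simv$loci, cohv)
  expect_identical(nrow(rec), 3195L)
})

test_that("peak-track coverage boundaries are exact", {
  loci <- make_test_loci()
  p0 <- sim_peak_track(loci, "H3K27ac", "liver", "s1", 0, seed = 1)
  expect_equal(nrow(p0), 0)
  p1 <- sim_peak_track(loci, "H3K27ac", "liver", "s1", 1, seed = 1)
  ev <- data.frame(chrom = c("chr1", "chr2"), first_pos = c(100L, 500L),
                   last_pos = c(250L, 500L), tissue = "liver", sample = "s1",
                   gene_id = c("geneA", "geneB"),
                   phase_set = c("ps1", "ps2"), stringsAsFactors = FALSE)
  ov <- overlap_events(ev, p1)
  expect_true(all(ov$n_marks == 1))
  expect_true(all(p1$start >= 0 & p1$end > p1$start))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(loci_per_gene = 0), "positive")
  expect_error(sim_config(ase_fraction = 1.2), "proportions")
  expect_error(sim_config(fold_change = 0), "fold_change")
  expect_error(sim_config(n_samples = 0), "positive")
  cfg <- sim_config(n_genes = 5, seed = 1)
  sim <- sim_phased_loci(cfg)
  bad <- sim$truth[-1, , drop = FALSE]
  expect_error(sim_locus_counts(sim$loci, bad, cfg), "truth")
})
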