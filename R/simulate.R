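# Ground-truth synthetic data: phased transcriptomes, read-count pileups,
# peak tracks, toy annotations, and multi-sample validation cohorts.
#
# Depth at each locus is Poisson(mean_depth); given depth, haplotype-1 reads
# are binomial with success probability 0.5 under the null and
# FC/(1+FC) for the favored haplotype of a truly imbalanced gene - the
# minimal model under which the pipeline's exact binomial test is correct.

#' Simulation configuration
#'
#' Holds every knob of the synthetic generator. Defaults mirror the study
#' conditions the pipeline targets: a multi-locus phased transcriptome with
#' 1-6 heterozygous SNPs per gene, moderate short-read depth, a ~1.5% rate
#' of truly imbalanced genes with a 4-fold expression ratio, and a 66-sample
#' validation cohort in which a discovery locus is heterozygous in ~80% of
#' samples.
#'
#' @param n_genes Number of genes (phased events) to simulate.
#' @param loci_per_gene Either a single count or a length-2 range
#'   `c(lo, hi)` of heterozygous loci per gene.
#' @param mean_depth Mean read depth per locus (Poisson mean).
#' @param ase_fraction Proportion of genes with true allelic imbalance.
#' @param fold_change True expression ratio of the favored to the disfavored
#'   haplotype for imbalanced genes (> 0; the favored-haplotype read fraction
#'   is `fold_change / (1 + fold_change)`).
#' @param n_samples Validation cohort size.
#' @param het_rate Probability that a discovery locus is heterozygous in a
#'   given cohort sample.
#' @param error_rate Per-read probability of a sequencing error scattering a
#'   read to a uniformly chosen non-haplotype base (default 0, off).
#' @param sex_chrom_fraction Proportion of genes placed on the sex
#'   chromosome (`chrX`).
#' @param n_autosomes Number of autosomes genes are spread over.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, loci_per_gene = c(1, 6), mean_depth = 50,
                       ase_fraction = 0.015, fold_change = 4, n_samples = 66,
                       het_rate = 0.8, error_rate = 0,
                       sex_chrom_fraction = 0.05, n_autosomes = 20,
                       seed = 1L) {
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 1) {
    stop("n_genes must be a positive count")
  }
  if (!length(loci_per_gene) %in% c(1L, 2L) || any(loci_per_gene < 1)) {
    stop("loci_per_gene must be a positive count or range")
  }
  if (length(loci_per_gene) == 2L && loci_per_gene[2] < loci_per_gene[1]) {
    stop("loci_per_gene range must be increasing")
  }
  for (p in c(ase_fraction = ase_fraction, het_rate = het_rate,
              error_rate = error_rate,
              sex_chrom_fraction = sex_chrom_fraction)) {
    if (is.na(p) || p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  }
  if (mean_depth < 0) stop("mean_depth must be non-negative")
  if (fold_change <= 0) stop("fold_change must be > 0")
  if (n_samples < 1) stop("n_samples must be a positive count")
  structure(list(
    n_genes = as.integer(n_genes),
    loci_per_gene = as.integer(loci_per_gene),
    mean_depth = mean_depth,
    ase_fraction = ase_fraction,
    fold_change = fold_change,
    n_samples = as.integer(n_samples),
    het_rate = het_rate,
    error_rate = error_rate,
    sex_chrom_fraction = sex_chrom_fraction,
    n_autosomes = as.integer(n_autosomes),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Gene layout constants: genes occupy non-overlapping 2 kb slots per
# chromosome, with heterozygous loci confined to the first 1 kb of the slot.
.SIM_SLOT <- 2000L
.SIM_SPAN <- 1000L
.SIM_OFFSET <- 1000L

#' Simulate a phased transcriptome with ground truth
#'
#' Lays genes out on `n_autosomes` autosomes plus `chrX` (at
#' `sex_chrom_fraction`), draws 1 or more heterozygous SNPs per gene with two
#' distinct haplotype bases and strictly increasing positions, and draws the
#' per-gene imbalance truth: each gene is truly imbalanced with probability
#' `ase_fraction`, with a random favored haplotype and true fold change
#' `fold_change`.
#'
#' @param config A [sim_config()].
#' @return A list with `loci` (het-locus data.frame: `chrom`, `pos`,
#'   `hap1_base`, `hap2_base`, `gene_id`, `phase_set`) and `truth`
#'   (data.frame: `gene_id`, `is_ase`, `true_fold_change`,
#'   `favored_haplotype`).
#' @export
sim_phased_loci <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  lpg <- config$loci_per_gene
  n_loci <- if (length(lpg) == 1L) rep(lpg, n) else
    sample(lpg[1]:lpg[2], n, replace = TRUE)

  on_sex <- runif(n) < config$sex_chrom_fraction
  chrom <- character(n)
  chrom[on_sex] <- "chrX"
  chrom[!on_sex] <- paste0("chr", ((which(!on_sex) - 1L) %% config$n_autosomes) + 1L)
  slot <- integer(n)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    slot[idx] <- seq_along(idx) - 1L
  }
  gene_start <- .SIM_OFFSET + slot * .SIM_SLOT

  gene_id <- sprintf("gene%05d", seq_len(n))
  loci_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_loci[i]
    pos <- sort(sample(gene_start[i]:(gene_start[i] + .SIM_SPAN - 1L), k))
    hap1 <- sample(ASE_BASES, k, replace = TRUE)
    hap2 <- vapply(hap1, function(b) sample(setdiff(ASE_BASES, b), 1L),
                   character(1), USE.NAMES = FALSE)
    loci_list[[i]] <- data.frame(
      chrom = chrom[i], pos = pos, hap1_base = hap1, hap2_base = hap2,
      gene_id = gene_id[i], phase_set = as.character(i),
      stringsAsFactors = FALSE
    )
  }
  loci <- do.call(rbind, loci_list)
  rownames(loci) <- NULL

  is_ase <- runif(n) < config$ase_fraction
  truth <- data.frame(
    gene_id = gene_id,
    is_ase = is_ase,
    true_fold_change = ifelse(is_ase, config$fold_change, 1),
    favored_haplotype = ifelse(is_ase, sample(1:2, n, replace = TRUE), 1L),
    stringsAsFactors = FALSE
  )
  validate_het_loci(loci)
  list(loci = loci, truth = truth)
}

#' Simulate per-locus read tallies given the imbalance truth
#'
#' Depth at each locus is Poisson(`mean_depth`). Conditional on depth,
#' haplotype-1 reads are binomial with probability 0.5 for null genes and
#' `FC/(1+FC)` when haplotype 1 is favored (`1/(1+FC)` when haplotype 2 is).
#' With `error_rate > 0` a binomial share of reads is scattered to a
#' uniformly chosen non-haplotype base; otherwise the two haplotype bases
#' account for the whole depth. The haplotype-1 base is taken as the
#' reference base of the pileup row.
#'
#' @param loci Het-locus data.frame from [sim_phased_loci()].
#' @param truth Ground-truth data.frame from [sim_phased_loci()].
#' @param config A [sim_config()].
#' @param seed Seed for this draw; defaults to `config$seed + 1`.
#' @return A locus-counts data.frame (`chrom`, `pos`, `ref_base`, `depth`,
#'   `A`, `C`, `G`, `T`, `N`, `del`).
#' @export
sim_locus_counts <- function(loci, truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  m <- match(loci$gene_id, truth$gene_id)
  if (anyNA(m)) stop("locus with gene absent from the ground truth")
  set.seed(seed)
  n <- nrow(loci)
  fc <- truth$true_fold_change[m]
  fav <- truth$favored_haplotype[m]
  p1 <- ifelse(truth$is_ase[m],
               ifelse(fav == 1L, fc / (1 + fc), 1 / (1 + fc)),
               0.5)
  depth <- rpois(n, config$mean_depth)
  n_err <- if (config$error_rate > 0) rbinom(n, depth, config$error_rate)
           else integer(n)
  n_hap <- depth - n_err
  a1 <- rbinom(n, n_hap, p1)
  a2 <- n_hap - a1

  counts <- data.frame(
    chrom = loci$chrom, pos = loci$pos, ref_base = loci$hap1_base,
    depth = depth, A = 0L, C = 0L, G = 0L, T = 0L, N = 0L, del = 0L,
    stringsAsFactors = FALSE
  )
  cm <- as.matrix(counts[, ASE_BASES])
  cm[cbind(seq_len(n), match(loci$hap1_base, ASE_BASES))] <- a1
  idx2 <- cbind(seq_len(n), match(loci$hap2_base, ASE_BASES))
  cm[idx2] <- cm[idx2] + a2
  if (any(n_err > 0L)) {
    for (i in which(n_err > 0L)) {
      pool <- setdiff(ASE_BASES, c(loci$hap1_base[i], loci$hap2_base[i]))
      err_b <- sample(pool, n_err[i], replace = TRUE)
      tb <- table(err_b)
      cm[i, names(tb)] <- cm[i, names(tb)] + as.integer(tb)
    }
  }
  counts[, ASE_BASES] <- cm
  counts
}

#' Simulate a histone-mark peak track over phased events
#'
#' Builds one peak per covered event, extending `flank` bp beyond the event's
#' first and last heterozygous positions, so that approximately
#' `coverage_fraction` of event regions are intersected. Intervals are
#' 0-based half-open, sorted, and merged if they touch.
#'
#' @param loci Het-locus data.frame.
#' @param mark Histone mark label (free-form; e.g. `"H3K27ac"`). Labels
#'   outside the four canonical marks only trigger a message.
#' @param tissue,sample_id Track labels.
#' @param coverage_fraction Proportion of event regions to cover, in [0, 1].
#' @param seed Integer seed.
#' @param flank Peak extension beyond the event region, in bp.
#' @return Peak data.frame (`chrom`, `start`, `end`, `mark`, `tissue`,
#'   `sample`), 0-based half-open.
#' @export
sim_peak_track <- function(loci, mark, tissue, sample_id, coverage_fraction,
                           seed, flank = 50L) {
  if (is.na(coverage_fraction) || coverage_fraction < 0 || coverage_fraction > 1) {
    stop("coverage_fraction must lie in [0, 1]")
  }
  canonical <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3")
  if (!mark %in% canonical) {
    message("note: mark '", mark, "' is not one of the four canonical marks")
  }
  regions <- event_regions(loci)
  set.seed(seed)
  covered <- if (coverage_fraction >= 1) rep(TRUE, nrow(regions))
             else runif(nrow(regions)) < coverage_fraction
  regions <- regions[covered, , drop = FALSE]
  if (nrow(regions) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mark = character(),
                      tissue = character(), sample = character(),
                      stringsAsFactors = FALSE))
  }
  start0 <- pmax(0L, regions$first_pos - 1L - as.integer(flank))
  end0 <- regions$last_pos + as.integer(flank)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(start = start0 + 1L, end = end0)
  ))
  peaks <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    mark = mark, tissue = tissue, sample = sample_id,
    stringsAsFactors = FALSE
  )
  peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
}

# Per-event (phase set) region spans, 1-based inclusive.
event_regions <- function(loci) {
  ps <- factor(loci$phase_set, levels = unique(loci$phase_set))
  data.frame(
    phase_set = levels(ps),
    gene_id = loci$gene_id[match(levels(ps), loci$phase_set)],
    chrom = loci$chrom[match(levels(ps), loci$phase_set)],
    first_pos = as.vector(tapply(loci$pos, ps, min)),
    last_pos = as.vector(tapply(loci$pos, ps, max)),
    n_loci = as.vector(tapply(loci$pos, ps, length)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-sample validation cohort at discovery loci
#'
#' Each of `n_samples` samples carries read counts only at loci drawn
#' heterozygous with probability `het_rate`. Depth and allele counts follow
#' the same Poisson/binomial model as [sim_locus_counts()], re-using the
#' discovery ground truth so truly imbalanced loci keep their favored
#' direction across samples.
#'
#' @param loci Het-locus data.frame of the discovery loci to re-test.
#' @param truth Ground-truth data.frame covering the loci's genes.
#' @param config A [sim_config()] (`n_samples`, `het_rate`, `mean_depth`,
#'   `error_rate` are used).
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return A data.frame of per-sample locus counts: `sample_id`, `chrom`,
#'   `pos`, `ref_base`, `depth`, `A`, `C`, `G`, `T`, `N`, `del`.
#' @export
sim_validation_cohort <- function(loci, truth, config,
                                  seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(loci) == 0L) stop("discovery loci must be nonempty")
  if (config$n_samples < 1L) stop("n_samples must be a positive count")
  set.seed(seed)
  out <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    het <- runif(nrow(loci)) < config$het_rate
    if (!any(het)) next
    sub <- loci[het, , drop = FALSE]
    cnt <- sim_locus_counts(sub, truth, config,
                            seed = sample.int(.Machine$integer.max, 1L))
    cnt$sample_id <- sprintf("val%02d", s)
    out[[s]] <- cnt
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(
      data.frame(chrom = character(), pos = integer(), ref_base = character(),
                 depth = integer(), A = integer(), C = integer(),
                 G = integer(), T = integer(), N = integer(), del = integer(),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = character(), stringsAsFactors = FALSE)
    )
  }
  rownames(out) <- NULL
  out[, c("sample_id", setdiff(names(out), "sample_id"))]
}

#' Simulate a toy transcript annotation over the phased loci
#'
#' Builds one single-exon transcript per gene spanning its heterozygous loci
#' with 200 bp of flanking sequence; 90% of transcripts carry a CDS inset
#' from the exon ends (leaving UTRs), the rest are non-coding. A random
#' reference genome is generated with the haplotype-1 base planted at every
#' locus, so codon-level consequence classification is exercised end to end.
#'
#' @param loci Het-locus data.frame.
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed + 3`.
#' @param coding_fraction Proportion of transcripts given a CDS.
#' @return A list with `features` (exon/CDS data.frame) and `genome`
#'   (named [Biostrings::DNAStringSet]); see [write_annotation()].
#' @export
sim_annotation <- function(loci, config, seed = config$seed + 3L,
                           coding_fraction = 0.9) {
  set.seed(seed)
  regions <- event_regions(loci)
  tx_start <- pmax(1L, regions$first_pos - 200L)
  tx_end <- regions$last_pos + 200L
  strand <- sample(c("+", "-"), nrow(regions), replace = TRUE)
  coding <- runif(nrow(regions)) < coding_fraction

  feat <- list()
  for (i in seq_len(nrow(regions))) {
    tid <- paste0(regions$gene_id[i], ".t1")
    feat[[length(feat) + 1L]] <- data.frame(
      chrom = regions$chrom[i], type = "exon", start = tx_start[i],
      end = tx_end[i], strand = strand[i], gene_id = regions$gene_id[i],
      transcript_id = tid, stringsAsFactors = FALSE
    )
    if (coding[i]) {
      # inset the CDS beyond the flank so edge loci fall in the UTRs
      inset <- min(300L, (tx_end[i] - tx_start[i] + 1L) %/% 4L)
      cs <- tx_start[i] + inset
      ce <- tx_end[i] - inset
      ce <- cs + (((ce - cs + 1L) %/% 3L) * 3L) - 1L   # full codons
      feat[[length(feat) + 1L]] <- data.frame(
        chrom = regions$chrom[i], type = "CDS", start = cs, end = ce,
        strand = strand[i], gene_id = regions$gene_id[i],
        transcript_id = tid, stringsAsFactors = FALSE
      )
    }
  }
  features <- do.call(rbind, feat)

  chrom_len <- tapply(features$end, features$chrom, max) + 100L
  seqs <- character(length(chrom_len))
  names(seqs) <- names(chrom_len)
  for (cn in names(chrom_len)) {
    chars <- sample(ASE_BASES, chrom_len[[cn]], replace = TRUE)
    sel <- loci$chrom == cn        # plant the haplotype-1 (reference) allele
    chars[loci$pos[sel]] <- loci$hap1_base[sel]
    seqs[[cn]] <- paste(chars, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  list(features = features, genome = genome)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits the phased VCF, an mpileup text file of simulated tallies, a truth
#' TSV, one BED peak track per canonical histone mark, and a toy GTF +
#' reference FASTA. Identical config (including seed) yields byte-identical
#' files.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param tissue Tissue label used for the peak tracks.
#' @param peak_coverage Named numeric vector of coverage fractions per mark.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_ase_fixtures <- function(dir, config, tissue = "liver",
                               peak_coverage = c(H3K27ac = 0.55,
                                                 H3K4me3 = 0.43,
                                                 H3K4me1 = 0.39,
                                                 H3K27me3 = 0.25)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- sim_phased_loci(config)
  counts <- sim_locus_counts(sim$loci, sim$truth, config)
  ann <- sim_annotation(sim$loci, config)

  paths <- c(
    vcf = file.path(dir, "phased_loci.vcf"),
    pileup = file.path(dir, "locus_counts.pileup"),
    truth = file.path(dir, "ground_truth.tsv"),
    gtf = file.path(dir, "transcripts.gtf"),
    fasta = file.path(dir, "reference.fa")
  )
  write_phased_vcf(sim$loci, paths[["vcf"]])
  write_mpileup(counts, paths[["pileup"]])
  write_tsv(sim$truth, paths[["truth"]])
  write_annotation(ann, gtf_path = paths[["gtf"]], fasta_path = paths[["fasta"]])
  for (k in seq_along(peak_coverage)) {
    mk <- names(peak_coverage)[k]
    p <- file.path(dir, paste0("peaks_", mk, ".bed"))
    write_bed_peaks(
      sim_peak_track(sim$loci, mk, tissue, "s1", peak_coverage[[k]],
                     seed = config$seed + 10L + k),
      p
    )
    paths[[paste0("peaks_", mk)]] <- p
  }
  invisible(paths)
}
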