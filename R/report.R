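# Summary tables, cross-context ASDEG detection, hypergeometric pathway
# over-representation, and end-to-end pipeline orchestration.

#' Per-tissue ASE summary table
#'
#' One row per tissue with the number of analyzable allele comparisons
#' (events passing the count prefilter), the number of significant ASE
#' events, and the percentage (2 decimals), sorted by descending percentage,
#' plus a global total row labelled `"all"`.
#'
#' @param events ASE-event data.frame from [ase_test()] (needs `tissue`,
#'   `prefilter_pass`, `significant`).
#' @return Data.frame with `tissue`, `allele_comparisons`, `ase_count`,
#'   `pct`.
#' @export
tissue_summary <- function(events) {
  tested <- events[events$prefilter_pass, , drop = FALSE]
  tissues <- unique(tested$tissue)
  rows <- lapply(tissues, function(tt) {
    sub <- tested[tested$tissue == tt, , drop = FALSE]
    data.frame(tissue = tt, allele_comparisons = nrow(sub),
               ase_count = sum(sub$significant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    tissue = "all", allele_comparisons = nrow(tested),
    ase_count = sum(tested$significant), stringsAsFactors = FALSE
  ))))
  out$pct <- ifelse(out$allele_comparisons > 0,
                    round(100 * out$ase_count / out$allele_comparisons, 2), 0)
  body <- out[out$tissue != "all", , drop = FALSE]
  body <- body[order(-body$pct, body$tissue), , drop = FALSE]
  out <- rbind(body, out[out$tissue == "all", , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Cross-context ASDEG table
#'
#' A gene is an ASDEG (allele-specific differentially expressed gene) if it
#' has at least one significant ASE event; genes significant in two or more
#' (tissue, sample) contexts are flagged multi-context. Also returns the
#' long-form |aeFC| matrix data behind a per-gene/per-context plot.
#'
#' @param events ASE-event data.frame from [ase_test()].
#' @return A list with `asdegs` (data.frame `gene_id`, `n_events`,
#'   `n_contexts`, `multi_context`), `n_multi_context`, and `cells`
#'   (long-form data.frame `gene_id`, `tissue`, `sample`, `abs_aefc`,
#'   `significant` restricted to ASDEG genes).
#' @export
asdeg_table <- function(events) {
  sig <- events[events$significant, , drop = FALSE]
  genes <- unique(sig$gene_id)
  asdegs <- data.frame(
    gene_id = genes,
    n_events = vapply(genes, function(g) sum(sig$gene_id == g), integer(1)),
    n_contexts = vapply(genes, function(g) {
      length(unique(paste(sig$tissue[sig$gene_id == g],
                          sig$sample[sig$gene_id == g])))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  asdegs$multi_context <- asdegs$n_contexts >= 2L
  asdegs <- asdegs[order(asdegs$gene_id), , drop = FALSE]
  rownames(asdegs) <- NULL
  cells <- events[events$gene_id %in% genes, , drop = FALSE]
  cells <- data.frame(
    gene_id = cells$gene_id, tissue = cells$tissue, sample = cells$sample,
    abs_aefc = abs(cells$aefc), significant = cells$significant,
    stringsAsFactors = FALSE
  )
  list(asdegs = asdegs, n_multi_context = sum(asdegs$multi_context),
       cells = cells)
}

#' Hypergeometric pathway over-representation test
#'
#' One-sided over-representation p-value per pathway:
#' `P(X >= n_overlap)` for `X` hypergeometric with population `n_universe`,
#' `n_pathway` successes and `n_input` draws. Significance is called at raw
#' `p <= alpha` by default; an optional BH adjustment is exposed.
#'
#' @param genes Character vector of input genes (e.g. ASDEGs of one tissue).
#' @param pathway_map Data.frame with `pathway_id` and `gene_id` columns
#'   (one row per membership).
#' @param universe Character vector of background genes; must contain
#'   `genes`. Pathway genes outside the universe are ignored; pathways with
#'   no universe genes are skipped.
#' @param alpha Significance cutoff on the (possibly adjusted) p-value.
#' @param adjust If `TRUE`, BH-adjust the p-values before calling
#'   significance.
#' @return Data.frame with `pathway_id`, `n_universe`, `n_pathway`,
#'   `n_input`, `n_overlap`, `p_value`, (optionally `adj_p`,) `significant`,
#'   sorted by p-value.
#' @export
enrich_pathways <- function(genes, pathway_map, universe, alpha = 0.05,
                            adjust = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  genes <- unique(genes)
  if (!all(genes %in% universe)) {
    stop("input genes must be contained in the universe")
  }
  n_uni <- length(universe)
  n_in <- length(genes)
  out <- lapply(unique(pathway_map$pathway_id), function(pw) {
    pw_genes <- intersect(unique(
      pathway_map$gene_id[pathway_map$pathway_id == pw]), universe)
    if (length(pw_genes) == 0L) return(NULL)
    n_pw <- length(pw_genes)
    n_ov <- length(intersect(pw_genes, genes))
    p <- phyper(n_ov - 1L, n_pw, n_uni - n_pw, n_in, lower.tail = FALSE)
    data.frame(pathway_id = pw, n_universe = n_uni, n_pathway = n_pw,
               n_input = n_in, n_overlap = n_ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(pathway_id = character(), n_universe = integer(),
                      n_pathway = integer(), n_input = integer(),
                      n_overlap = integer(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  if (adjust) {
    out$adj_p <- bh_adjust(out$p_value)
    out$significant <- out$adj_p <= alpha
  } else {
    out$significant <- out$p_value <= alpha
  }
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full synthetic ASE pipeline
#'
#' Orchestrates every stage on generated data: phased loci + ground truth,
#' per-tissue pileup counts, haplotype tallying, sex-chromosome exclusion,
#' the significance cascade, optional consequence annotation with the
#' intronic/intergenic exclusion, histone-peak overlap of significant
#' events, validation of one tissue's significant loci in an independent
#' cohort, and the summary tables.
#'
#' @param config A [sim_config()].
#' @param tissues Character vector of tissue labels; counts are drawn
#'   independently per tissue from the same phased loci and truth.
#' @param sample_id Sample label for the discovery dataset.
#' @param marks Named numeric vector: peak coverage fraction per histone
#'   mark used for the synthetic tracks.
#' @param annotate If `TRUE`, generate a toy annotation, classify locus
#'   consequences, and drop events whose loci are solely
#'   intronic/intergenic.
#' @param validate_tissue Tissue whose significant loci are re-tested in the
#'   synthetic cohort; `NULL` skips validation.
#' @param outdir Optional directory: every table is also written as TSV.
#' @param ... Passed to [ase_test()] (thresholds, BH scope).
#' @return A list with `loci`, `truth`, `expression` (per-tissue haplotype
#'   expression), `dropped_sex` (events excluded as sex-chromosomal),
#'   `events` (all tissues), `consequences` (or `NULL`), `overlaps`,
#'   `combinations`, `tissue_summary`, `asdeg`, `validation` (records +
#'   summary, or `NULL`).
#' @export
run_ase_pipeline <- function(config, tissues = "liver", sample_id = "s1",
                             marks = c(H3K27ac = 0.55, H3K4me3 = 0.43,
                                       H3K4me1 = 0.39, H3K27me3 = 0.25),
                             annotate = FALSE, validate_tissue = NULL,
                             outdir = NULL, ...) {
  stopifnot(inherits(config, "sim_config"))
  sim <- sim_phased_loci(config)
  split_loci <- drop_sex_chromosomes(sim$loci)

  events <- NULL
  expression <- NULL
  for (k in seq_along(tissues)) {
    counts <- sim_locus_counts(sim$loci, sim$truth, config,
                               seed = config$seed + 100L + k)
    expr <- tally_events(split_loci$kept, counts)
    expr$tissue <- tissues[k]
    expr$sample <- sample_id
    ev <- ase_test(expr, ...)
    expression <- rbind(expression, expr)
    events <- rbind(events, ev)
  }

  consequences <- NULL
  if (annotate) {
    ann <- sim_annotation(sim$loci, config)
    models <- transcript_models(ann$features)
    consequences <- classify_consequences(split_loci$kept, models,
                                          genome = ann$genome)
    kept <- filter_nonfunctional(consequences)
    keep_keys <- paste(kept$chrom, kept$pos)
    loci_keys <- paste(split_loci$kept$chrom, split_loci$kept$pos)
    ok_ps <- unique(split_loci$kept$phase_set[loci_keys %in% keep_keys])
    events <- events[events$phase_set %in% ok_ps, , drop = FALSE]
  }

  sig <- events[events$significant, , drop = FALSE]
  peaks <- NULL
  for (tt in tissues) {
    for (k in seq_along(marks)) {
      peaks <- rbind(peaks, sim_peak_track(
        split_loci$kept, names(marks)[k], tt, sample_id, marks[[k]],
        seed = config$seed + 200L + k
      ))
    }
  }
  overlaps <- overlap_events(sig, peaks, match = "sample")
  combinations <- combination_table(overlaps)

  validation <- NULL
  if (!is.null(validate_tissue)) {
    sig_t <- sig[sig$tissue == validate_tissue, , drop = FALSE]
    disc_loci <- split_loci$kept[split_loci$kept$phase_set %in%
                                   sig_t$phase_set, , drop = FALSE]
    if (nrow(disc_loci) > 0L) {
      cohort <- sim_validation_cohort(disc_loci, sim$truth, config)
      records <- validate_loci(disc_loci, cohort)
      disc_counts <- sim_locus_counts(disc_loci, sim$truth, config,
                                      seed = config$seed + 100L +
                                        match(validate_tissue, tissues))
      m <- match(paste(disc_loci$chrom, disc_loci$pos),
                 paste(disc_counts$chrom, disc_counts$pos))
      base_mat <- as.matrix(disc_counts[, ASE_BASES])
      d1 <- base_mat[cbind(m, match(disc_loci$hap1_base, ASE_BASES))]
      d2 <- base_mat[cbind(m, match(disc_loci$hap2_base, ASE_BASES))]
      disc_dir <- data.frame(
        locus_id = paste0(disc_loci$chrom, ":", disc_loci$pos),
        direction = sign(aefc(d1, d2)), stringsAsFactors = FALSE
      )
      validation <- list(records = records,
                         summary = summarize_validation(records, disc_dir))
    }
  }

  result <- list(
    loci = sim$loci, truth = sim$truth, expression = expression,
    dropped_sex = split_loci$dropped, events = events,
    consequences = consequences, overlaps = overlaps,
    combinations = combinations, tissue_summary = tissue_summary(events),
    asdeg = asdeg_table(events), validation = validation
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(result$loci, file.path(outdir, "phased_loci.tsv"))
    write_tsv(result$truth, file.path(outdir, "ground_truth.tsv"))
    write_ase_events(result$events, file.path(outdir, "ase_events.tsv"))
    write_tsv(result$overlaps, file.path(outdir, "mark_overlaps.tsv"))
    write_tsv(result$tissue_summary, file.path(outdir, "tissue_summary.tsv"))
    if (!is.null(result$validation)) {
      write_tsv(result$validation$records,
                file.path(outdir, "validation_records.tsv"))
    }
  }
  result
}
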