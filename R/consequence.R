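# Variant consequence classification of heterozygous loci against
# transcript models: UTR / coding / splice-region / intronic / intergenic
# terms, with codon-level calls when a reference sequence is supplied.
# Splice-region windows follow Ensembl's definitions: 1-3 bp inside an exon
# from an intron-adjacent boundary, and 1-8 bp into the intron.

comp_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

order_terms <- function(terms) {
  terms <- unique(terms)
  terms[order(match(terms, ASE_CONSEQUENCE_TERMS))]
}

#' Classify the variant consequence of heterozygous loci
#'
#' Assigns each locus one or more consequence terms against every
#' overlapping transcript, unioning terms across transcripts:
#' \itemize{
#'   \item inside a CDS (reference sequence given): both alleles' codons are
#'     translated - same amino acid gives `synonymous_variant`, a new stop
#'     `stop_gained`, a lost stop `stop_lost`, otherwise `missense_variant`;
#'     without a reference (or a CDS whose length is not a multiple of 3,
#'     which draws a warning) the codon terms are suppressed and the locus
#'     gets `coding_sequence_variant`
#'   \item exonic 5' of the CDS start (strand-aware) gives
#'     `5_prime_UTR_variant`; 3' of the CDS end `3_prime_UTR_variant`
#'   \item exonic within 1-3 bp of an intron-adjacent exon boundary, or
#'     intronic within 1-8 bp of an exon, additionally gets
#'     `splice_region_variant`
#'   \item an exon of a transcript without CDS gives
#'     `non_coding_transcript_exon_variant`; inside a transcript but outside
#'     its exons `intron_variant`; no overlapping transcript
#'     `intergenic_variant`
#' }
#'
#' @param loci Het-locus data.frame (`chrom`, `pos`, `hap1_base`,
#'   `hap2_base`, ...).
#' @param models A `tx_models` object from [read_gtf()] /
#'   [transcript_models()].
#' @param genome Optional named [Biostrings::DNAStringSet] (or named
#'   character vector) of reference sequences; required for codon-level
#'   terms.
#' @return A consequence-record data.frame: `chrom`, `pos`, `hap1_base`,
#'   `hap2_base`, `gene_id` (empty string for intergenic loci), and a `terms`
#'   list-column of consequence terms.
#' @export
classify_consequences <- function(loci, models, genome = NULL) {
  stopifnot(inherits(models, "tx_models"))
  if (!is.null(genome)) {
    nm <- names(genome)
    genome <- as.character(genome)
    if (is.null(names(genome))) names(genome) <- nm
    if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
      stop("genome sequences must be named by chromosome")
    }
  }
  tx <- models$tx
  exon_by_tx <- split(models$exons, models$exons$transcript_id)
  cds_by_tx <- split(models$cds, models$cds$transcript_id)

  n <- nrow(loci)
  terms_list <- vector("list", n)
  gene_ids <- character(n)
  for (i in seq_len(n)) {
    pos <- loci$pos[i]
    hit <- which(tx$chrom == loci$chrom[i] & tx$start <= pos & tx$end >= pos)
    if (length(hit) == 0L) {
      terms_list[[i]] <- "intergenic_variant"
      gene_ids[i] <- ""
      next
    }
    terms <- character(0)
    genes <- character(0)
    for (h in hit) {
      tid <- tx$transcript_id[h]
      t_terms <- classify_locus_tx(
        pos, loci$hap1_base[i], loci$hap2_base[i],
        exons = exon_by_tx[[tid]], cds = cds_by_tx[[tid]],
        strand = tx$strand[h],
        chromseq = if (!is.null(genome)) genome[[loci$chrom[i]]] else NULL,
        tid = tid
      )
      terms <- c(terms, t_terms)
      genes <- c(genes, tx$gene_id[h])
    }
    terms_list[[i]] <- order_terms(terms)
    gene_ids[i] <- paste(unique(genes), collapse = ",")
  }
  out <- loci[, intersect(c("chrom", "pos", "hap1_base", "hap2_base"),
                          names(loci)), drop = FALSE]
  out$gene_id <- gene_ids
  out$terms <- terms_list
  rownames(out) <- NULL
  out
}

# Consequence terms of one locus against one transcript.
classify_locus_tx <- function(pos, a1, a2, exons, cds, strand, chromseq,
                              tid = "") {
  exons <- exons[order(exons$start), , drop = FALSE]
  n_ex <- nrow(exons)
  ex_i <- which(exons$start <= pos & exons$end >= pos)
  terms <- character(0)

  if (length(ex_i) == 1L) {
    has_cds <- !is.null(cds) && nrow(cds) > 0L
    if (!has_cds) {
      terms <- "non_coding_transcript_exon_variant"
    } else {
      cds <- cds[order(cds$start), , drop = FALSE]
      cds_lo <- min(cds$start); cds_hi <- max(cds$end)
      if (pos < cds_lo) {
        terms <- if (strand == "+") "5_prime_UTR_variant" else "3_prime_UTR_variant"
      } else if (pos > cds_hi) {
        terms <- if (strand == "+") "3_prime_UTR_variant" else "5_prime_UTR_variant"
      } else if (any(cds$start <= pos & cds$end >= pos)) {
        terms <- codon_terms(pos, a1, a2, cds, strand, chromseq, tid)
      } else {
        # inside the CDS genomic span but not in a coding part of this exon
        terms <- "coding_sequence_variant"
      }
    }
    # splice region: 1-3 bp inside the exon from an intron-adjacent boundary
    right_intron <- ex_i < n_ex
    left_intron <- ex_i > 1L
    if ((right_intron && exons$end[ex_i] - pos <= 2L) ||
        (left_intron && pos - exons$start[ex_i] <= 2L)) {
      terms <- c(terms, "splice_region_variant")
    }
  } else {
    terms <- "intron_variant"
    # distance into the intron from the flanking exons
    prev_end <- max(exons$end[exons$end < pos])
    next_start <- min(exons$start[exons$start > pos])
    d <- min(pos - prev_end, next_start - pos)
    if (d <= 8L) terms <- c(terms, "splice_region_variant")
  }
  terms
}

# Codon-level terms for a CDS locus; falls back to coding_sequence_variant
# when no reference is available or the CDS length is not a codon multiple.
codon_terms <- function(pos, a1, a2, cds, strand, chromseq, tid = "") {
  if (is.null(chromseq)) return("coding_sequence_variant")
  widths <- cds$end - cds$start + 1L
  if (sum(widths) %% 3L != 0L) {
    warning("CDS length of transcript ", tid,
            " is not a multiple of 3; codon terms suppressed")
    return("coding_sequence_variant")
  }
  part <- which(cds$start <= pos & cds$end >= pos)
  cds_seq <- paste(substring(chromseq, cds$start, cds$end), collapse = "")
  if (strand == "+") {
    rel <- sum(widths[seq_len(part - 1L)]) + (pos - cds$start[part] + 1L)
  } else {
    cds_seq <- revcomp(cds_seq)
    rel <- sum(widths[-seq_len(part)]) + (cds$end[part] - pos + 1L)
  }
  a1c <- if (strand == "+") a1 else comp_base(a1)
  a2c <- if (strand == "+") a2 else comp_base(a2)

  idx0 <- (rel - 1L) %/% 3L
  off <- (rel - 1L) %% 3L
  codon <- substr(cds_seq, idx0 * 3L + 1L, idx0 * 3L + 3L)
  ref_base <- substr(codon, off + 1L, off + 1L)
  if (a1c == ref_base) { ref_a <- a1c; alt_a <- a2c }
  else if (a2c == ref_base) { ref_a <- a2c; alt_a <- a1c }
  else { ref_a <- a1c; alt_a <- a2c }

  sub_at <- function(cod, b) { substr(cod, off + 1L, off + 1L) <- b; cod }
  aa <- function(cod) {
    if (grepl("[^ACGT]", cod) || nchar(cod) != 3L) return(NA_character_)
    Biostrings::GENETIC_CODE[[cod]]
  }
  aa_ref <- aa(sub_at(codon, ref_a))
  aa_alt <- aa(sub_at(codon, alt_a))
  if (is.na(aa_ref) || is.na(aa_alt)) return("coding_sequence_variant")
  if (aa_ref == aa_alt) return("synonymous_variant")
  if (aa_alt == "*") return("stop_gained")
  if (aa_ref == "*") return("stop_lost")
  "missense_variant"
}

#' Drop loci annotated solely as intronic or intergenic
#'
#' A record is removed iff its term set is contained in
#' `{intron_variant, intergenic_variant}`; retained records have those two
#' terms stripped from their sets, so only annotations supported by
#' transcribed sequence remain.
#'
#' @param records Consequence-record data.frame from
#'   [classify_consequences()].
#' @return The filtered data.frame.
#' @export
filter_nonfunctional <- function(records) {
  nonfunc <- c("intron_variant", "intergenic_variant")
  only_nonfunc <- vapply(records$terms,
                         function(t) all(t %in% nonfunc), logical(1))
  out <- records[!only_nonfunc, , drop = FALSE]
  out$terms <- lapply(out$terms, function(t) setdiff(t, nonfunc))
  rownames(out) <- NULL
  out
}

#' Tabulate consequence-term combinations
#'
#' Counts records by their exact term combination (terms joined with
#' `" & "` in severity order) and reports each combination's percentage of
#' the total, rounded to two decimals.
#'
#' @param records Consequence-record data.frame with a `terms` list-column
#'   (or a character `terms` column of `&`-joined labels).
#' @return Data.frame with `terms`, `count`, `percent`, sorted by
#'   descending count.
#' @export
summarize_consequences <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(terms = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  labels <- if (is.list(records$terms)) {
    vapply(records$terms, function(t) paste(order_terms(t), collapse = " & "),
           character(1))
  } else {
    as.character(records$terms)
  }
  tab <- table(labels)
  out <- data.frame(
    terms = names(tab),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out$percent <- round(100 * out$count / sum(out$count), 2)
  out <- out[order(-out$count, out$terms), , drop = FALSE]
  rownames(out) <- NULL
  out
}
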