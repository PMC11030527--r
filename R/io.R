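# Readers and writers for the standard formats the pipeline touches.
# Coordinate conventions: VCF/GTF/pileup positions are 1-based inclusive,
# BED intervals are 0-based half-open; every function documents which it
# takes and returns.

#' Read phased heterozygous SNPs from a VCF
#'
#' Keeps biallelic SNP records with a phased heterozygous genotype
#' (`0|1` or `1|0`) for the first sample. For `0|1` haplotype 1 carries the
#' REF base; `1|0` swaps the assignment. Records are grouped into phased
#' events by the `PS` (phase set) FORMAT tag when present, falling back to a
#' `GENE` INFO tag, then to one group per record. Unphased heterozygous
#' genotypes (`0/1`) are skipped with a warning.
#'
#' @param path Path to a VCF (4.x) file.
#' @return A het-locus data.frame with columns `chrom`, `pos` (1-based),
#'   `hap1_base`, `hap2_base`, `gene_id`, `phase_set`.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) < 1L) stop("VCF has no sample columns: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  if (any(n_alt == 1L)) {
    alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field: ", path)
  gt <- gt[, 1L]

  is_snp <- nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% ASE_BASES & alt1 %in% ASE_BASES
  phased_het <- gt %in% c("0|1", "1|0")
  n_unphased <- sum(gt %in% c("0/1", "1/0") & is_snp)
  if (n_unphased > 0L) {
    warning(n_unphased, " unphased heterozygous record(s) skipped")
  }
  keep <- is_snp & phased_het
  if (!any(keep)) {
    return(empty_het_loci())
  }

  swap <- gt[keep] == "1|0"
  hap1 <- ifelse(swap, alt1[keep], ref[keep])
  hap2 <- ifelse(swap, ref[keep], alt1[keep])

  ps <- VariantAnnotation::geno(vcf)$PS
  ps <- if (!is.null(ps)) as.character(ps[keep, 1L]) else rep(NA_character_, sum(keep))
  gene <- VariantAnnotation::info(vcf)$GENE
  gene <- if (!is.null(gene)) as.character(gene)[keep] else rep(NA_character_, sum(keep))

  phase_set <- ps
  phase_set[is.na(phase_set)] <- gene[is.na(phase_set)]
  phase_set[is.na(phase_set)] <- paste0("rec", which(keep)[is.na(phase_set)])
  gene_id <- gene
  gene_id[is.na(gene_id)] <- phase_set[is.na(gene_id)]

  loci <- data.frame(
    chrom = chrom[keep], pos = pos[keep],
    hap1_base = hap1, hap2_base = hap2,
    gene_id = gene_id, phase_set = phase_set,
    stringsAsFactors = FALSE
  )
  loci <- loci[order(match(loci$phase_set, unique(loci$phase_set)), loci$pos), ]
  rownames(loci) <- NULL
  validate_het_loci(loci)
  loci
}

empty_het_loci <- function() {
  data.frame(
    chrom = character(), pos = integer(),
    hap1_base = character(), hap2_base = character(),
    gene_id = character(), phase_set = character(),
    stringsAsFactors = FALSE
  )
}

validate_het_loci <- function(loci) {
  req <- c("chrom", "pos", "hap1_base", "hap2_base", "gene_id", "phase_set")
  miss <- setdiff(req, names(loci))
  if (length(miss)) stop("het-locus table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(loci$pos < 1L)) stop("het-locus positions must be >= 1")
  if (any(loci$hap1_base == loci$hap2_base)) {
    stop("heterozygous locus with identical haplotype bases")
  }
  bad <- !(loci$hap1_base %in% ASE_BASES) | !(loci$hap2_base %in% ASE_BASES)
  if (any(bad)) stop("non-ACGT haplotype base at ", sum(bad), " locus/loci")
  dup <- unlist(lapply(split(loci$pos, loci$phase_set),
                       function(p) any(duplicated(p))))
  if (any(dup)) stop("duplicate position within a phase set")
  invisible(loci)
}

#' Write phased heterozygous loci as a VCF
#'
#' Emits one phased `0|1` genotype per locus with REF = haplotype-1 base and
#' ALT = haplotype-2 base, a `GENE` INFO tag, and an integer `PS` phase-set
#' tag (phase sets numbered by first appearance).
#'
#' @param loci Het-locus data.frame (see [read_phased_vcf()]).
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(loci, path, sample_name = "sample1") {
  validate_het_loci(loci)
  ps_int <- match(loci$phase_set, unique(loci$phase_set))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapase",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene identifier\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste0("##contig=<ID=", unique(loci$chrom), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- paste(
    loci$chrom, loci$pos, ".", loci$hap1_base, loci$hap2_base, ".", "PASS",
    paste0("GENE=", loci$gene_id), "GT:PS", paste0("0|1:", ps_int),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a samtools mpileup text file into per-locus nucleotide tallies
#'
#' Parses the six-column mpileup dialect (chrom, 1-based pos, reference base,
#' depth, base string, base qualities) and decodes the base-string grammar:
#' `.`/`,` count toward the reference base; letters toward that base
#' (case-folded); `^X` read-start markup consumes the following
#' mapping-quality character; `$` read-end markup is consumed; `+n<seq>` and
#' `-n<seq>` indel runs are consumed without counting; `*` is tallied as a
#' deletion (not a nucleotide); `>`/`<` reference skips consume depth but are
#' not tallied. Bases whose Phred quality is below `min_base_quality` are
#' excluded from the tallies (they still count toward the reported depth).
#'
#' @param path Path to a 6-column mpileup text file.
#' @param min_base_quality Minimum Phred base quality for a base to be
#'   tallied; defaults to 13, the samtools default.
#' @return A locus-counts data.frame with columns `chrom`, `pos`, `ref_base`,
#'   `depth`, `A`, `C`, `G`, `T`, `N`, `del`.
#' @export
read_mpileup <- function(path, min_base_quality = 13) {
  if (!file.exists(path)) stop("mpileup file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- data.frame(
    chrom = character(n), pos = integer(n), ref_base = character(n),
    depth = integer(n), A = integer(n), C = integer(n), G = integer(n),
    T = integer(n), N = integer(n), del = integer(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) stop("malformed mpileup line ", i, ": ", lines[i])
    bases <- if (length(f) >= 5L) f[5] else ""
    quals <- if (length(f) >= 6L) f[6] else ""
    if (bases == "*" && quals == "*") { bases <- ""; quals <- "" }
    tal <- decode_pileup_bases(bases, quals, toupper(f[3]), min_base_quality,
                               where = paste0(f[1], ":", f[2], " (line ", i, ")"))
    out$chrom[i] <- f[1]
    out$pos[i] <- as.integer(f[2])
    out$ref_base[i] <- toupper(f[3])
    out$depth[i] <- as.integer(f[4])
    out[i, c("A", "C", "G", "T", "N", "del")] <- as.list(tal)
  }
  out
}

# Decode one mpileup base string against its quality string. Returns an
# integer vector c(A, C, G, T, N, del) of quality-passing tallies.
decode_pileup_bases <- function(bases, quals, ref, min_bq, where = "") {
  tal <- setNames(integer(6), c("A", "C", "G", "T", "N", "del"))
  if (!nzchar(bases)) {
    if (nzchar(quals)) stop("pileup bases/quality length mismatch at ", where)
    return(tal)
  }
  ch <- strsplit(bases, "")[[1]]
  qv <- if (nzchar(quals)) utf8ToInt(quals) - 33L else integer(0)
  i <- 1L; qi <- 0L; len <- length(ch)
  while (i <= len) {
    c0 <- ch[i]
    if (c0 == "^") {            # read start + mapping-quality char
      i <- i + 2L
    } else if (c0 == "$") {     # read end
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {   # indel run: digits then sequence
      j <- i + 1L
      while (j <= len && ch[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L) stop("malformed indel in pileup at ", where)
      nn <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + nn
    } else {                    # a depth-consuming base entry
      qi <- qi + 1L
      q <- if (qi <= length(qv)) qv[qi] else 0L
      if (qi > length(qv) && length(qv) > 0L) {
        stop("pileup bases/quality length mismatch at ", where)
      }
      pass <- length(qv) == 0L || q >= min_bq
      if (c0 == "." || c0 == ",") {
        if (pass && ref %in% ASE_BASES) tal[ref] <- tal[ref] + 1L
      } else if (c0 == "*") {
        if (pass) tal["del"] <- tal["del"] + 1L
      } else if (toupper(c0) %in% c(ASE_BASES, "N")) {
        if (pass) tal[toupper(c0)] <- tal[toupper(c0)] + 1L
      } else if (c0 == ">" || c0 == "<") {
        # reference skip: consumes depth and quality, never tallied
      } else {
        stop("unrecognised pileup character '", c0, "' at ", where)
      }
      i <- i + 1L
    }
  }
  if (length(qv) > 0L && qi != length(qv)) {
    stop("pileup bases/quality length mismatch at ", where)
  }
  tal
}

#' Write locus tallies as mpileup-dialect text
#'
#' Encodes reference-matching reads as `.`, other nucleotides as letters,
#' deletions as `*`, and any depth in excess of the tallies as reference
#' skips (`>`), with a uniform high base quality (`I`, Phred 40). Reading the
#' file back with [read_mpileup()] recovers the tallies and depth exactly.
#'
#' @param counts Locus-counts data.frame (see [read_mpileup()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mpileup <- function(counts, path) {
  n <- nrow(counts)
  lines <- character(n)
  for (i in seq_len(n)) {
    ref <- counts$ref_base[i]
    parts <- character(0)
    for (b in ASE_BASES) {
      k <- counts[[b]][i]
      if (k > 0L) parts <- c(parts, strrep(if (b == ref) "." else b, k))
    }
    if (!is.null(counts$N) && counts$N[i] > 0L) {
      parts <- c(parts, strrep("N", counts$N[i]))
    }
    ndel <- if (is.null(counts$del)) 0L else counts$del[i]
    if (ndel > 0L) parts <- c(parts, strrep("*", ndel))
    used <- sum(counts[i, intersect(c("A", "C", "G", "T", "N", "del"),
                                    names(counts))])
    extra <- max(0L, counts$depth[i] - used)
    if (extra > 0L) parts <- c(parts, strrep(">", extra))
    bstr <- paste(parts, collapse = "")
    qstr <- strrep("I", nchar(bstr))
    lines[i] <- paste(counts$chrom[i], counts$pos[i], ref, counts$depth[i],
                      bstr, qstr, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+3 histone-peak file
#'
#' Expects columns chrom, start, end (0-based half-open), mark, tissue,
#' sample. Trailing annotation columns beyond six are ignored; missing mark /
#' tissue / sample columns are filled with `"."`.
#'
#' @param path Path to a BED file.
#' @return Peak data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `mark`, `tissue`, `sample`.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(x) < 3L) stop("BED file needs at least 3 columns: ", path)
  for (k in seq_len(max(0L, 6L - ncol(x)))) x[[ncol(x) + 1L]] <- "."
  peaks <- data.frame(
    chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
    end = as.integer(x[[3]]), mark = as.character(x[[4]]),
    tissue = as.character(x[[5]]), sample = as.character(x[[6]]),
    stringsAsFactors = FALSE
  )
  if (any(peaks$start < 0L)) stop("negative BED start coordinate in ", path)
  if (any(peaks$end <= peaks$start)) stop("BED interval with end <= start in ", path)
  peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
}

#' Write peaks as BED3+3
#' @param peaks Peak data.frame (see [read_bed_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  write.table(peaks[, c("chrom", "start", "end", "mark", "tissue", "sample")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GTF
#'
#' Imports a GTF (1-based inclusive coordinates) and assembles per-transcript
#' exon and CDS structures for consequence classification.
#'
#' @param path Path to a GTF file.
#' @return An object of class `tx_models`: a list with `exons` and `cds`
#'   (GRangesList split by transcript) and `tx` (a data.frame of transcript
#'   spans with `transcript_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  transcript_models(gr)
}

#' Assemble transcript models from an annotation GRanges or feature table
#'
#' @param gr A GRanges (or data.frame with columns `chrom`, `start`, `end`,
#'   `strand`) carrying metadata columns `type` (containing `exon` and
#'   optionally `CDS` features), `transcript_id` and `gene_id`.
#' @return A `tx_models` list; see [read_gtf()].
#' @export
transcript_models <- function(gr) {
  if (is.data.frame(gr)) {
    feat <- gr
  } else {
    feat <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      type = as.character(gr$type),
      gene_id = as.character(gr$gene_id),
      transcript_id = as.character(gr$transcript_id),
      stringsAsFactors = FALSE
    )
  }
  exons <- feat[feat$type == "exon", , drop = FALSE]
  cds <- feat[feat$type == "CDS", , drop = FALSE]
  if (nrow(exons) == 0L) stop("annotation contains no exon features")
  if (any(exons$end < exons$start)) stop("exon with end < start")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
  tx_ids <- unique(exons$transcript_id)
  first <- match(tx_ids, exons$transcript_id)
  tx <- data.frame(
    transcript_id = tx_ids,
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    start = as.vector(tapply(exons$start, exons$transcript_id, min)[tx_ids]),
    end = as.vector(tapply(exons$end, exons$transcript_id, max)[tx_ids]),
    strand = exons$strand[first],
    stringsAsFactors = FALSE
  )
  rownames(tx) <- NULL
  structure(list(exons = exons, cds = cds, tx = tx), class = "tx_models")
}

#' Write a table as TSV / read it back
#'
#' Thin wrappers around [utils::write.table()] / [utils::read.delim()] used
#' for every tabular intermediate; round-trips of character, integer, double
#' and logical columns are lossless. List-columns of character vectors (for
#' example consequence term sets) are collapsed with `" & "` on write.
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` returns a
#'   data.frame.
#' @export
write_tsv <- function(x, path) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) {
      x[[j]] <- vapply(x[[j]], paste, character(1), collapse = " & ")
    }
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write transcript models and a reference sequence for a toy annotation
#'
#' @param annotation A list with `features` (data.frame of exon/CDS rows:
#'   `chrom`, `type`, `start`, `end`, `strand`, `gene_id`, `transcript_id`)
#'   and `genome` (a named [Biostrings::DNAStringSet]).
#' @param gtf_path,fasta_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a character vector of the paths written.
#' @export
write_annotation <- function(annotation, gtf_path = NULL, fasta_path = NULL) {
  written <- character(0)
  if (!is.null(gtf_path)) {
    f <- annotation$features
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     f$gene_id, f$transcript_id)
    lines <- paste(f$chrom, "hapase", f$type, f$start, f$end, ".",
                   f$strand, ".", attrs, sep = "\t")
    writeLines(lines, gtf_path)
    written <- c(written, gtf_path)
  }
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(annotation$genome, fasta_path)
    written <- c(written, fasta_path)
  }
  invisible(written)
}
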