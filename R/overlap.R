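# Intersection of ASE event regions with histone-mark peak tracks and
# upset-style combination counting.

#' Overlap ASE event regions with histone-mark peaks
#'
#' An event's region runs from its first to its last heterozygous position
#' (1-based inclusive; a single-locus event is a 1 bp region). A mark is hit
#' iff at least 1 bp of the region intersects at least one peak of that mark
#' from the matching tissue (and sample, when `match = "sample"`); no
#' reciprocal-overlap fraction is required. Peaks are 0-based half-open.
#' Events whose tissue (or tissue/sample) has no peak track at all get an
#' empty hit set with a notice.
#'
#' @param events ASE-event data.frame with `chrom`, `first_pos`, `last_pos`,
#'   `tissue`, `sample` columns (e.g. from [ase_test()]).
#' @param peaks Peak data.frame (`chrom`, `start`, `end`, `mark`, `tissue`,
#'   `sample`), e.g. from [read_bed_peaks()] or [sim_peak_track()]; several
#'   tracks may simply be row-bound.
#' @param match `"sample"` to require tissue and sample to agree between
#'   event and track, `"tissue"` for tissue only.
#' @return A mark-overlap data.frame: the events' identifying columns plus
#'   `marks_hit` (`&`-joined sorted mark labels, `""` when none) and
#'   `n_marks`.
#' @export
overlap_events <- function(events, peaks, match = c("sample", "tissue")) {
  match <- match.arg(match)
  ev_key <- if (match == "sample") paste(events$tissue, events$sample)
            else events$tissue
  pk_key <- if (match == "sample") paste(peaks$tissue, peaks$sample)
            else peaks$tissue

  no_track <- !(ev_key %in% unique(pk_key))
  if (any(no_track)) {
    message("note: ", sum(no_track),
            " event(s) have no peak track for their tissue/sample")
  }

  marks <- sort(unique(peaks$mark))
  hit <- matrix(FALSE, nrow(events), length(marks),
                dimnames = list(NULL, marks))
  if (nrow(events) > 0L && nrow(peaks) > 0L) {
    chrom_lv <- union(events$chrom, peaks$chrom)   # shared seqlevels
    ev_gr <- GenomicRanges::GRanges(
      factor(events$chrom, levels = chrom_lv),
      IRanges::IRanges(events$first_pos, events$last_pos)
    )
    for (key in unique(pk_key)) {
      ev_sel <- which(ev_key == key)
      if (length(ev_sel) == 0L) next
      psub <- peaks[pk_key == key, , drop = FALSE]
      for (mk in unique(psub$mark)) {
        msub <- psub[psub$mark == mk, , drop = FALSE]
        pk_gr <- GenomicRanges::GRanges(
          factor(msub$chrom, levels = chrom_lv),
          IRanges::IRanges(msub$start + 1L, msub$end)
        )
        ov <- GenomicRanges::findOverlaps(ev_gr[ev_sel], pk_gr)
        hit[ev_sel[unique(S4Vectors::queryHits(ov))], mk] <- TRUE
      }
    }
  }
  marks_hit <- apply(hit, 1L, function(z) paste(marks[z], collapse = " & "))
  id_cols <- intersect(c("gene_id", "phase_set", "tissue", "sample", "chrom",
                         "first_pos", "last_pos"), names(events))
  out <- events[, id_cols, drop = FALSE]
  out$marks_hit <- if (nrow(events)) marks_hit else character(0)
  out$n_marks <- rowSums(hit)
  rownames(out) <- NULL
  out
}

#' Tabulate histone-mark combinations over events
#'
#' Upset-style exact-combination counts plus per-mark marginal totals, the
#' number and percentage of events overlapping at least one mark, and -
#' among those - the number and percentage overlapping two or more marks.
#' All percentages carry explicit denominators in the output.
#'
#' @param overlaps Mark-overlap data.frame from [overlap_events()].
#' @return A list with `combinations` (data.frame `marks_hit`, `count`),
#'   `marginals` (data.frame `mark`, `count`), `n_events`, `n_any_mark`,
#'   `pct_any_mark` (of all events), `n_multi_mark`, `pct_multi_mark` (of
#'   any-mark events).
#' @export
combination_table <- function(overlaps) {
  n_events <- nrow(overlaps)
  with_mark <- overlaps[overlaps$n_marks > 0L, , drop = FALSE]
  n_any <- nrow(with_mark)
  n_multi <- sum(with_mark$n_marks >= 2L)

  combos <- if (n_any > 0L) {
    tab <- sort(table(with_mark$marks_hit), decreasing = TRUE)
    data.frame(marks_hit = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(marks_hit = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  all_marks <- sort(unique(unlist(strsplit(with_mark$marks_hit, " & ",
                                           fixed = TRUE))))
  marginals <- data.frame(
    mark = all_marks,
    count = vapply(all_marks, function(mk) {
      sum(vapply(strsplit(with_mark$marks_hit, " & ", fixed = TRUE),
                 function(z) mk %in% z, logical(1)))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(marginals) <- NULL
  list(
    combinations = combos,
    marginals = marginals,
    n_events = n_events,
    n_any_mark = n_any,
    pct_any_mark = if (n_events > 0L) round(100 * n_any / n_events, 2) else 0,
    n_multi_mark = n_multi,
    pct_multi_mark = if (n_any > 0L) round(100 * n_multi / n_any, 2) else 0
  )
}
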