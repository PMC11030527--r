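# The statistical core: allele expression fold change (aeFC), exact binomial
# test of allelic balance, Benjamini-Hochberg FDR, and the three-part
# significance cascade.

#' Minimum-count prefilter
#'
#' An event is analyzable only if at least one of its two haplotype
#' expression values meets the threshold (default 10); events where neither
#' does are excluded from testing.
#'
#' @param a1,a2 Non-negative haplotype read counts (vectorized).
#' @param min_count Threshold the larger count must reach.
#' @return Logical vector.
#' @export
ase_prefilter <- function(a1, a2, min_count = 10) {
  if (any(c(a1, a2) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  pmax(a1, a2) >= min_count
}

#' Allele expression fold change (aeFC)
#'
#' `log2(a1) - log2(a2)`, with no pseudocount: when exactly one count is
#' zero the result is a signed infinity, and when both are zero it is `NaN`
#' (such an event can never be significant). Swapping the alleles negates
#' the value exactly.
#'
#' @param a1,a2 Non-negative haplotype read counts (vectorized).
#' @return Numeric vector of log2 fold changes.
#' @export
aefc <- function(a1, a2) {
  if (any(c(a1, a2) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  log2(a1) - log2(a2)
}

#' Exact two-sided binomial test of allelic balance
#'
#' Under the null hypothesis that the two alleles of a gene are expressed
#' equally, `a1` is binomial with success probability `p` (default 0.5) on
#' `a1 + a2` trials. The two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one. Pairs with `a1 + a2 = 0`
#' are undefined and return `NA`.
#'
#' @param a1,a2 Non-negative haplotype read counts (vectorized).
#' @param p Null success probability (exposed for reference-bias
#'   corrections; default 0.5).
#' @return Numeric vector of p-values.
#' @export
binom_ase_p <- function(a1, a2, p = 0.5) {
  if (length(a1) != length(a2)) stop("a1 and a2 must have equal length")
  if (any(c(a1, a2) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  mapply(function(x, y) {
    if (is.na(x) || is.na(y) || x + y == 0) return(NA_real_)
    binom.test(x, x + y, p = p)$p.value
  }, as.integer(round(a1)), as.integer(round(a2)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input order is preserved and adjusted values are
#' capped at 1. `NA` p-values stay `NA` and do not count toward the family
#' size.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Three-part significance rule
#'
#' An event shows significant allele-specific expression iff the absolute
#' aeFC is at least `fc_min`, the adjusted p-value is at most `alpha`, and
#' at least one haplotype expression value is at least `exp_min`. Infinite
#' aeFC (one allele silent) passes the fold-change comparison; `NaN` (both
#' zero) never does.
#'
#' @param fc Vector of aeFC values.
#' @param adj_p Vector of BH-adjusted p-values.
#' @param a1,a2 Haplotype read counts.
#' @param fc_min Minimum |aeFC| (log2 scale; default 2, a 4-fold ratio).
#' @param alpha Adjusted-p cutoff.
#' @param exp_min Minimum for the larger expression value.
#' @return Logical vector.
#' @export
classify_ase <- function(fc, adj_p, a1, a2, fc_min = 2, alpha = 0.05,
                         exp_min = 5) {
  ok_fc <- !is.na(fc) & !is.nan(fc) & abs(fc) >= fc_min
  ok_p <- !is.na(adj_p) & adj_p <= alpha
  ok_exp <- pmax(a1, a2) >= exp_min
  ok_fc & ok_p & ok_exp
}

#' Run the full ASE significance cascade on haplotype expression values
#'
#' Applies, in order: the minimum-count prefilter, aeFC, the exact binomial
#' test (computed only for prefiltered events), BH adjustment, and the
#' three-part significance rule. The BH family is all prefiltered events
#' within one `(tissue, sample)` dataset (`bh_scope = "dataset"`, the
#' default) or the whole table (`"global"`).
#'
#' @param expr Haplotype-expression data.frame from [tally_events()], or any
#'   data.frame with `allele1_exp` and `allele2_exp` columns.
#' @param tissue,sample Labels attached to every event when `expr` has no
#'   `tissue` / `sample` columns of its own.
#' @param min_count Prefilter threshold (see [ase_prefilter()]).
#' @param fc_min,alpha,exp_min Significance cascade thresholds (see
#'   [classify_ase()]).
#' @param bh_scope `"dataset"` or `"global"` BH family.
#' @param null_p Null success probability for the binomial test.
#' @return An ASE-event data.frame: the input columns plus `tissue`,
#'   `sample`, `aefc`, `p_value`, `adj_p`, `prefilter_pass`, `significant`.
#' @export
ase_test <- function(expr, tissue = "tissue1", sample = "sample1",
                     min_count = 10, fc_min = 2, alpha = 0.05, exp_min = 5,
                     bh_scope = c("dataset", "global"), null_p = 0.5) {
  bh_scope <- match.arg(bh_scope)
  ev <- as.data.frame(expr, stringsAsFactors = FALSE)
  if (!all(c("allele1_exp", "allele2_exp") %in% names(ev))) {
    stop("expr must carry allele1_exp and allele2_exp columns")
  }
  if (!"tissue" %in% names(ev)) ev$tissue <- tissue
  if (!"sample" %in% names(ev)) ev$sample <- sample

  ev$prefilter_pass <- ase_prefilter(ev$allele1_exp, ev$allele2_exp,
                                     min_count = min_count)
  ev$aefc <- aefc(ev$allele1_exp, ev$allele2_exp)
  ev$p_value <- NA_real_
  sel <- ev$prefilter_pass
  ev$p_value[sel] <- binom_ase_p(ev$allele1_exp[sel], ev$allele2_exp[sel],
                                 p = null_p)
  ev$adj_p <- NA_real_
  fam <- if (bh_scope == "dataset") interaction(ev$tissue, ev$sample,
                                                drop = TRUE)
         else factor(rep(1L, nrow(ev)))
  for (g in levels(fam)) {
    gi <- which(fam == g)
    ev$adj_p[gi] <- bh_adjust(ev$p_value[gi])
  }
  ev$significant <- classify_ase(ev$aefc, ev$adj_p, ev$allele1_exp,
                                 ev$allele2_exp, fc_min = fc_min,
                                 alpha = alpha, exp_min = exp_min)
  ev
}

# Sentinel used to store signed-infinite aeFC values in TSV output.
.AEFC_INF_SENTINEL <- 1e9

#' Write / read an ASE-event table as TSV
#'
#' Signed-infinite aeFC values are stored as the sentinel `±1e9` together
#' with an `aefc_infinite` flag column; reading restores the infinities.
#' `NaN` aeFC (both counts zero) round-trips as `NA`.
#'
#' @param events ASE-event data.frame from [ase_test()].
#' @param path File path.
#' @return `write_ase_events` returns `path` invisibly; `read_ase_events`
#'   the restored data.frame.
#' @export
write_ase_events <- function(events, path) {
  ev <- events
  inf <- is.infinite(ev$aefc)
  ev$aefc_infinite <- inf
  ev$aefc[inf] <- sign(ev$aefc[inf]) * .AEFC_INF_SENTINEL
  ev$aefc[is.nan(ev$aefc)] <- NA_real_
  write_tsv(ev, path)
}

#' @rdname write_ase_events
#' @export
read_ase_events <- function(path) {
  ev <- read_tsv(path)
  if ("aefc_infinite" %in% names(ev)) {
    inf <- !is.na(ev$aefc_infinite) & ev$aefc_infinite
    ev$aefc[inf] <- sign(ev$aefc[inf]) * Inf
    ev$aefc_infinite <- NULL
  }
  ev
}
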