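# Shared fixtures and independent oracles for the test suite.

# Independent two-sided binomial oracle: enumerate all outcomes k = 0..n and
# sum the probabilities of those no more likely than the observed outcome.
# Uses choose() directly so it shares no code path with binom.test().
oracle_binom_two_sided <- function(k, n, p = 0.5) {
  probs <- vapply(0:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
                  numeric(1))
  obs <- probs[k + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Independent BH step-up oracle applied by the textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent hypergeometric upper-tail oracle by direct mass enumeration.
oracle_hyper_ge <- function(overlap, n_universe, n_pathway, n_input) {
  ks <- overlap:min(n_pathway, n_input)
  sum(vapply(ks, function(k) {
    choose(n_pathway, k) * choose(n_universe - n_pathway, n_input - k) /
      choose(n_universe, n_input)
  }, numeric(1)))
}

# A small deterministic het-locus table spread over two phase sets.
make_test_loci <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 250L, 500L),
    hap1_base = c("A", "C", "G"),
    hap2_base = c("G", "T", "A"),
    gene_id = c("geneA", "geneA", "geneB"),
    phase_set = c("ps1", "ps1", "ps2"),
    stringsAsFactors = FALSE
  )
}

# Locus-count rows matching make_test_loci().
make_test_counts <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 250L, 500L),
    ref_base = c("A", "C", "G"),
    depth = c(40L, 40L, 20L),
    A = c(30L, 0L, 5L), C = c(0L, 25L, 0L), G = c(10L, 0L, 15L),
    T = c(0L, 15L, 0L), N = c(0L, 0L, 0L), del = c(0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

# Toy plus-strand coding transcript on a 600 bp chromosome:
# exon1 101..220, exon2 301..520; CDS 151..220 + 301..460 (230+... = 70+160
# = 230 -> not multiple of 3, so widths are chosen below to sum to 228).
# CDS parts: 151..220 (70 bp) and 301..458 (158 bp) = 228 bp = 76 codons.
make_toy_tx <- function(strand = "+") {
  feat <- data.frame(
    chrom = "chrT",
    type = c("exon", "exon", "CDS", "CDS"),
    start = c(101L, 301L, 151L, 301L),
    end = c(220L, 520L, 220L, 458L),
    strand = strand,
    gene_id = "toyG",
    transcript_id = "toyT",
    stringsAsFactors = FALSE
  )
  transcript_models(feat)
}

# Deterministic toy chromosome: repeats of "GAACCT" (600 bp), so codon
# content at any CDS offset is known by arithmetic.
make_toy_genome <- function() {
  c(chrT = paste(rep("GAACCT", 100), collapse = ""))
}

random_loci_counts <- function(n_events, seed, loci_range = c(1, 4),
                               depth = 60) {
  cfg <- sim_config(n_genes = n_events, loci_per_gene = loci_range,
                    mean_depth = depth, ase_fraction = 0.3,
                    fold_change = 5, seed = seed)
  sim <- sim_phased_loci(cfg)
  counts <- sim_locus_counts(sim$loci, sim$truth, cfg)
  list(loci = sim$loci, counts = counts, truth = sim$truth, config = cfg)
}
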