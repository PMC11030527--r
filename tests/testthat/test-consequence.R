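# The toy chromosome repeats GAACCT, so the codon at any CDS offset is known
# by arithmetic: CDS starts at 151 (a "G"), giving codons GAA CCT GAA ...

toy_locus <- function(pos, a1, a2) {
  data.frame(chrom = "chrT", pos = as.integer(pos), hap1_base = a1,
             hap2_base = a2, gene_id = "toyG", phase_set = "ps",
             stringsAsFactors = FALSE)
}

test_that("codon-level calls distinguish synonymous, missense and stops", {
  models <- make_toy_tx()
  genome <- make_toy_genome()
  # third codon position 153: GAA(Glu) -> GAG(Glu)
  rec <- classify_consequences(toy_locus(153, "A", "G"), models, genome)
  expect_equal(rec$terms[[1]], "synonymous_variant")
  # second codon position 152: GAA(Glu) -> GTA(Val)
  rec <- classify_consequences(toy_locus(152, "A", "T"), models, genome)
  expect_equal(rec$terms[[1]], "missense_variant")
  # first codon position 151: GAA(Glu) -> TAA(stop)
  rec <- classify_consequences(toy_locus(151, "G", "T"), models, genome)
  expect_equal(rec$terms[[1]], "stop_gained")
  # stop_lost is the mirror call when haplotype 1 carries the stop
  rec <- classify_consequences(toy_locus(151, "T", "G"), models, genome)
  expect_equal(rec$terms[[1]], "stop_gained")   # ref allele is G in genome
  expect_equal(rec$gene_id, "toyG")
  # neither allele matches the reference: haplotype 1 is treated as the
  # baseline, so TAA(stop) -> CAA(Gln) is a lost stop
  rec <- classify_consequences(toy_locus(151, "T", "C"), models, genome)
  expect_equal(rec$terms[[1]], "stop_lost")
})

test_that("UTR, intron, splice-region and intergenic calls follow position", {
  models <- make_toy_tx()
  genome <- make_toy_genome()
  cases <- list(
    list(120, "5_prime_UTR_variant"),          # exon1 before CDS start
    list(470, "3_prime_UTR_variant"),          # exon2 past CDS end
    list(250, "intron_variant"),               # deep intron
    list(50, "intergenic_variant"),            # outside the transcript
    list(590, "intergenic_variant")
  )
  for (cs in cases) {
    rec <- classify_consequences(toy_locus(cs[[1]], "A", "C"), models, genome)
    expect_true(cs[[2]] %in% rec$terms[[1]], info = paste("pos", cs[[1]]))
  }
  # splice windows: 1-3 bp inside an intron-adjacent exon boundary
  rec <- classify_consequences(toy_locus(219, "A", "C"), models, genome)
  expect_true("splice_region_variant" %in% rec$terms[[1]])
  rec <- classify_consequences(toy_locus(302, "A", "C"), models, genome)
  expect_true("splice_region_variant" %in% rec$terms[[1]])
  # 1-8 bp into the intron
  rec <- classify_consequences(toy_locus(224, "A", "C"), models, genome)
  expect_setequal(rec$terms[[1]], c("intron_variant", "splice_region_variant"))
  rec <- classify_consequences(toy_locus(229, "A", "C"), models, genome)
  expect_equal(rec$terms[[1]], "intron_variant")   # 9 bp in, outside window
  # exon1 start (101) abuts no intron: no splice term
  rec <- classify_consequences(toy_locus(102, "A", "C"), models, genome)
  expect_false("splice_region_variant" %in% rec$terms[[1]])
})

test_that("a transcript without CDS yields the non-coding exon term", {
  feat <- data.frame(chrom = "chrT", type = "exon", start = 101L, end = 220L,
                     strand = "+", gene_id = "ncG", transcript_id = "ncT",
                     stringsAsFactors = FALSE)
  models <- transcript_models(feat)
  rec <- classify_consequences(toy_locus(150, "A", "C"), models,
                               make_toy_genome())
  expect_equal(rec$terms[[1]], "non_coding_transcript_exon_variant")
})

test_that("codon terms are suppressed without a reference or on broken CDS", {
  models <- make_toy_tx()
  rec <- classify_consequences(toy_locus(153, "A", "G"), models, genome = NULL)
  expect_equal(rec$terms[[1]], "coding_sequence_variant")

  feat <- data.frame(chrom = "chrT", type = c("exon", "CDS"),
                     start = c(101L, 151L), end = c(320L, 260L),
                     strand = "+", gene_id = "g", transcript_id = "t",
                     stringsAsFactors = FALSE)   # CDS length 110, not %% 3
  broken <- transcript_models(feat)
  expect_warning(
    rec <- classify_consequences(toy_locus(200, "A", "G"), broken,
                                 make_toy_genome()),
    "multiple of 3")
  expect_equal(rec$terms[[1]], "coding_sequence_variant")
})

test_that("strand mirroring with complemented alleles preserves the terms", {
  L <- 600L
  genome_fwd <- make_toy_genome()
  mirror_seq <- paste(rev(strsplit(chartr("ACGT", "TGCA", genome_fwd[[1]]),
                                   "")[[1]]), collapse = "")
  feat_fwd <- data.frame(
    chrom = "chrT", type = c("exon", "exon", "CDS", "CDS"),
    start = c(101L, 301L, 151L, 301L), end = c(220L, 520L, 220L, 458L),
    strand = "+", gene_id = "toyG", transcript_id = "toyT",
    stringsAsFactors = FALSE
  )
  feat_rev <- feat_fwd
  feat_rev$start <- L + 1L - feat_fwd$end
  feat_rev$end <- L + 1L - feat_fwd$start
  feat_rev$strand <- "-"
  m_fwd <- transcript_models(feat_fwd)
  m_rev <- transcript_models(feat_rev)
  set.seed(41)
  for (pos in c(120L, 152L, 153L, 219L, 224L, 250L, 470L, 50L)) {
    a <- sample(c("A", "C", "G", "T"), 2)
    rec_f <- suppressWarnings(classify_consequences(
      toy_locus(pos, a[1], a[2]), m_fwd, genome_fwd))
    rec_r <- suppressWarnings(classify_consequences(
      toy_locus(L + 1L - pos, chartr("ACGT", "TGCA", a[1]),
                chartr("ACGT", "TGCA", a[2])),
      m_rev, c(chrT = mirror_seq)))
    expect_true(setequal(rec_f$terms[[1]], rec_r$terms[[1]]),
                label = paste("terms match at pos", pos))
  }
})

test_that("terms are unioned over overlapping transcripts", {
  feat <- rbind(
    data.frame(chrom = "chrT", type = "exon", start = 101L, end = 220L,
               strand = "+", gene_id = "gA", transcript_id = "tA",
               stringsAsFactors = FALSE),
    data.frame(chrom = "chrT", type = c("exon", "CDS"),
               start = c(60L, 110L), end = c(250L, 220L), strand = "+",
               gene_id = "gB", transcript_id = "tB",
               stringsAsFactors = FALSE)
  )
  models <- transcript_models(feat)
  rec <- classify_consequences(toy_locus(153, "A", "G"), models,
                               make_toy_genome())
  expect_true("non_coding_transcript_exon_variant" %in% rec$terms[[1]])
  expect_true(any(c("synonymous_variant", "missense_variant", "stop_gained",
                    "stop_lost") %in% rec$terms[[1]]))
  expect_setequal(strsplit(rec$gene_id, ",")[[1]], c("gA", "gB"))
})

test_that("intronic/intergenic-only records are excluded, others cleaned", {
  records <- data.frame(chrom = "chr1", pos = 1:4,
                        gene_id = c("g1", "g2", "", "g3"),
                        stringsAsFactors = FALSE)
  records$terms <- list(
    "intron_variant",
    c("intron_variant", "missense_variant"),
    "intergenic_variant",
    "3_prime_UTR_variant"
  )
  out <- filter_nonfunctional(records)
  expect_equal(out$pos, c(2L, 4L))
  expect_equal(out$terms[[1]], "missense_variant")
  expect_equal(out$terms[[2]], "3_prime_UTR_variant")
})

test_that("consequence summaries count exact term combinations", {
  records <- data.frame(chrom = "chr1", pos = 1:10, stringsAsFactors = FALSE)
  records$terms <- c(
    rep(list("3_prime_UTR_variant"), 4),
    rep(list(c("splice_region_variant", "synonymous_variant")), 3),
    rep(list("missense_variant"), 2),
    list("stop_gained")
  )
  tab <- summarize_consequences(records)
  expect_equal(tab$count[tab$terms == "3_prime_UTR_variant"], 4L)
  expect_equal(
    tab$count[tab$terms == "splice_region_variant & synonymous_variant"], 3L)
  expect_equal(sum(tab$count), 10L)
  expect_equal(sum(tab$percent), 100, tolerance = 0.05)
  single <- summarize_consequences(records[1, , drop = FALSE])
  expect_equal(single$percent, 100)
  empty <- summarize_consequences(records[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})
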