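# breakpoint_analysis: annotation partition, reconciliation, read support,
# mono-allelic QC, clustering

test_that("annotate_breakend assigns the documented categories", {
  genes <- list(toy1 = toy_gene("+"))
  ctx <- annotate_breakend(break_end("chrT", 1100L, "retained-left"), genes)
  expect_equal(ctx$category, "EXONIC")
  expect_equal(ctx$exon_index, 1L)
  expect_equal(annotate_breakend(break_end("chrT", 1500L, "retained-left"),
                                 genes)$category, "INTRONIC")
  expect_equal(annotate_breakend(break_end("chrT", 5000L, "retained-left"),
                                 genes)$category, "INTERGENIC")
  # half-open tie-break: position == exon end is not in the exon
  expect_equal(annotate_breakend(break_end("chrT", 1200L, "retained-left"),
                                 genes)$category, "INTRONIC")
})

test_that("annotation is a partition matching an interval oracle", {
  sim <- make_genome(seed = 12)
  set.seed(120)
  pos <- sample(0:49999, 2000)
  chrom <- sample(c("chr1", "chr2"), 2000, replace = TRUE)
  for (i in seq_along(pos)) {
    got <- annotate_breakend(break_end(chrom[i], pos[i], "retained-left"),
                             sim$genes)
    expect_equal(got$category, oracle_annotate(chrom[i], pos[i], sim$genes))
    expect_equal(!is.na(got$gene_id), got$category != "INTERGENIC")
    expect_equal(!is.na(got$exon_index), got$category == "EXONIC")
  }
})

test_that("spiked FOS-like exon-4 breaks annotate as exon 4", {
  for (seed in 1:5) {
    sc <- simulate_scenario("fos-like", seed = seed)
    ctx <- annotate_breakend(sc$dna[[1]]$end1, sc$sim$genes)
    expect_equal(ctx$category, "EXONIC")
    expect_equal(ctx$exon_index, 4L)
  }
})

test_that("reconcile retains only orientation-consistent nearby pairs", {
  mk <- function(p1, p2, o1 = "retained-left", o2 = "retained-right",
                 ev = "DNA")
    rearrangement(break_end("chr1", p1, o1), break_end("chr2", p2, o2),
                  evidence = ev)
  d <- mk(1000L, 5000L)
  expect_length(reconcile(list(d), list(mk(1000L, 5000L, ev = "RNA")), 0L), 1L)
  shifted <- mk(1005L, 5005L, ev = "RNA")
  expect_length(reconcile(list(d), list(shifted), 10L), 1L)
  expect_length(reconcile(list(d), list(shifted), 2L), 0L)
  flipped <- mk(1000L, 5000L, o1 = "retained-right", o2 = "retained-left",
                ev = "RNA")
  expect_length(reconcile(list(d), list(flipped), 10L), 0L)
  expect_error(reconcile(list(d), list(d), -1L), "slack")
})

test_that("reconcile equals the brute-force matcher and is idempotent", {
  set.seed(77)
  mk <- function(p1, p2, o1, o2, ev)
    rearrangement(break_end("chr1", p1, o1), break_end("chr2", p2, o2),
                  evidence = ev)
  os <- c("retained-left", "retained-right")
  for (rep_i in 1:20) {
    dna <- lapply(1:6, function(i)
      mk(sample(1e4, 1), sample(1e4, 1), sample(os, 1), sample(os, 1), "DNA"))
    rna <- lapply(1:6, function(i) {
      base <- dna[[sample(6, 1)]]
      rearrangement(
        break_end(base$end1$chrom, base$end1$pos + sample(-15:15, 1),
                  base$end1$orientation),
        break_end(base$end2$chrom, base$end2$pos + sample(-15:15, 1),
                  base$end2$orientation),
        evidence = "RNA")
    })
    got <- reconcile(dna, rna, 10L)
    want <- oracle_reconcile(dna, rna, 10L)
    expect_equal(length(got), length(want))
    # output is a subset of DNA calls, positions untouched
    for (g in got) {
      expect_true(any(vapply(dna, function(d)
        identical(d$end1$pos, g$end1$pos) &&
          identical(d$end2$pos, g$end2$pos), logical(1))))
      expect_equal(g$evidence, "both")
    }
    # idempotence on (x, x, 0)
    self <- reconcile(dna, dna, 0L)
    expect_length(self, length(dna))
  }
})

test_that("read support counts match spiked truth and ignore distant reads", {
  r <- rearrangement(break_end("chr1", 5000L, "retained-left"),
                     break_end("chr2", 21000L, "retained-right"))
  expect_equal(count_supporting_reads(
    simulate_reads(r, n_split = 0L, n_pairs = 0L), r),
    c(split = 0L, discordant = 0L))
  reads <- simulate_reads(r, n_split = 3L, n_pairs = 2L, n_decoy = 4L)
  expect_equal(count_supporting_reads(reads, r),
               c(split = 3L, discordant = 2L))
  far <- rearrangement(break_end("chr1", 15000L, "retained-left"),
                       break_end("chr2", 31000L, "retained-right"))
  expect_equal(count_supporting_reads(
    simulate_reads(r, 3L, 2L), far), c(split = 0L, discordant = 0L))
})

test_that("mono-allelic QC clusters nearby breaks and flags distant ones", {
  genes <- list(toy1 = toy_gene("+"))
  mk <- function(p) rearrangement(break_end("chrT", p, "retained-left"),
                                  break_end("chrZ", 9e6, "retained-right"),
                                  sample_id = "s1")
  one <- check_monoallelic(list(mk(1100L)), genes, slack = 10L)
  expect_equal(one$n_breakpoints, 1L)
  expect_false(one$flagged)

  merged <- check_monoallelic(list(mk(1100L), mk(1103L)), genes, slack = 10L)
  expect_equal(merged$n_breakpoints, 1L)

  split2 <- check_monoallelic(list(mk(1010L), mk(1900L)), genes, slack = 10L)
  expect_equal(split2$n_breakpoints, 2L)
  expect_true(split2$flagged)
})

test_that("minimal_cluster_window is max - min + 1", {
  expect_equal(minimal_cluster_window(42L), 1L)
  expect_equal(minimal_cluster_window(c(100L, 150L, 299L)), 200L)
  expect_error(minimal_cluster_window(integer()), "no break ends")
  # six spiked breaks within the 200 bp exon-4 window stay within 200 bp
  sim <- make_genome(seed = 13)
  e4 <- fosl_exon4(sim)
  set.seed(130)
  pos <- e4$start + sample(30:229, 6)
  expect_lte(minimal_cluster_window(pos), 200L)
})
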