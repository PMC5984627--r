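# synthetic_data: determinism, designed structures, spiking, coverage,
# pileups and copy-number emission

test_that("make_genome is deterministic and places the designed genes", {
  a <- make_genome(seed = 1)
  b <- make_genome(seed = 1)
  expect_identical(as.character(a$genome), as.character(b$genome))
  d1 <- withr::local_tempfile(); d2 <- withr::local_tempfile()
  write_annotation(a$genes, d1); write_annotation(b$genes, d2)
  expect_identical(readLines(d1), readLines(d2))

  two <- make_genome(seed = 2, n_genes = 2)
  expect_length(two$genes, 2L)
  bodies <- lapply(two$genes, function(g) g$body)
  expect_false(iv_overlaps(bodies[[1]], bodies[[2]]))
})

test_that("the FOS-like gene has 4 exons and elements 3' of the break window", {
  sim <- make_genome(seed = 3)
  g <- sim$genes$FOSL
  expect_equal(nrow(g$exons), 4L)
  expect_setequal(g$regulatory_elements$label,
                  c("instability_determinant", "AU_rich_element"))
  # break window: exon-4 offsets 30..230 => transcript 550..750
  window_end_tx <- 520L + 230L
  expect_true(all(g$regulatory_elements$start >= window_end_tx))
})

test_that("the partner region holds exactly the planted AATAAA and a valid cleavage", {
  for (seed in c(1, 9, 33)) {
    sim <- make_genome(seed = seed)
    fp <- sim$truth$fos_partner
    seq <- genome_sequence(sim$genome, fp$region)
    hits <- fp$region$start + scan_polya_motifs(seq)
    expect_equal(hits, fp$motif)
    off <- fp$cleavage - (fp$motif + 6L - 1L)
    expect_gte(off, 10L); expect_lte(off, 30L)
  }
})

test_that("spike_rearrangement obeys the contig arithmetic and its guards", {
  sim <- make_genome(seed = 4)
  g <- sim$genes$FOSL
  partner <- genomic_interval("chr2", 21000L, 22000L)

  # identity case: empty insert, partner sequence = reference partner slice
  sp <- spike_rearrangement(sim, "FOSL", g$exons$start[4] + 50L, partner)
  five <- genome_sequence(sim$genome,
                          genomic_interval("chr1", g$body$start,
                                           g$exons$start[4] + 50L))
  expect_identical(sp$contig,
                   paste0(five, genome_sequence(sim$genome, partner)))

  expect_error(
    spike_rearrangement(sim, "FOSL", g$body$start - 10L, partner),
    "outside the named gene")
  expect_error(
    spike_rearrangement(sim, "FOSL", g$exons$start[4],
                        genomic_interval("chr1", g$body$start, g$body$end)),
    "overlaps the source gene")
})

test_that("contig length bookkeeping holds over 100 random spikes", {
  sim <- make_genome(seed = 6)
  g <- sim$genes$FOSL
  set.seed(60)
  for (i in 1:100) {
    bp <- sample(g$body$start:(g$body$end - 1L), 1L)
    w <- sample(50:2000, 1L)
    s0 <- sample(0:40000, 1L)
    partner <- genomic_interval("chr2", s0, s0 + w)
    ins <- paste(sample(c("A", "C", "G", "T"), sample(0:5, 1L),
                        replace = TRUE), collapse = "")
    sp <- spike_rearrangement(sim, "FOSL", bp, partner, insert = ins)
    expect_equal(nchar(sp$contig),
                 (bp - g$body$start) + nchar(ins) + w)
  }
})

test_that("noiseless coverage is a hard cliff; noisy decays; seeds reproduce", {
  region <- genomic_interval("chr2", 0L, 1000L)
  tx <- genomic_interval("chr2", 100L, 500L)
  tr <- simulate_coverage(region, tx, mean_depth = 100, noise = 0)
  expect_true(all(tr$values[101:500] == 100))
  expect_true(all(tr$values[501:1000] == 0))
  expect_true(all(tr$values[1:100] == 0))

  t1 <- simulate_coverage(region, tx, mean_depth = 50, noise = 1, seed = 7)
  t2 <- simulate_coverage(region, tx, mean_depth = 50, noise = 1, seed = 7)
  expect_identical(t1$values, t2$values)
})

test_that("carrier/non-carrier coverage ratio clears the fold threshold", {
  sc <- simulate_scenario("fos-like", seed = 8)
  fp <- sc$truth$fos_partner
  i1 <- fp$junction - fp$region$start + 1L
  i2 <- fp$cleavage - fp$region$start + 1L
  carrier_mean <- mean(sc$tracks$tumour1$values[i1:i2])
  others <- vapply(sc$tracks[-1], function(t) mean(t$values[i1:i2]),
                   numeric(1))
  expect_gte(carrier_mean, 5 * max(mean(others), 1))
})

test_that("pileup allele fractions follow the requested ASE ratio", {
  snps <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                     ref = c("A", "C"), alt = c("G", "T"))
  pu <- simulate_pileup(snps, depth = 10000L, ase_ratio = 0.5, seed = 9)
  frac <- sum(pu$base[pu$pos == 100] == "G") / 10000
  expect_lt(abs(frac - 0.5), 0.02)

  pu1 <- simulate_pileup(snps, depth = 500L, ase_ratio = 1.0, seed = 9)
  expect_equal(sum(pu1$base %in% c("A", "C")), 0L)
})

test_that("spiked copy-number events appear verbatim in the emitted table", {
  sim <- make_genome(seed = 10)
  ev <- list(list(interval = genomic_interval("chr2", 10000L, 10500L),
                  total_cn = 6L, minor_cn = 1L))
  cn <- simulate_cn(sim, ev)
  d <- withr::local_tempfile(fileext = ".tsv")
  write_cn_segments(cn, d)
  back <- read_cn_segments(d)
  hit <- back[back$total_cn == 6L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 10000L)
  expect_equal(hit$end, 10500L)
  # background is diploid
  expect_true(all(back$total_cn[back$total_cn != 6L] == 2L))
})
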