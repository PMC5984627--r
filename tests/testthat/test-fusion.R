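# fusion_transcript: assembly, exonisation, translation/classification,
# frame arithmetic, regulatory-element loss

fos_fusion <- function(seed = 21, offset = 50L, insert = "") {
  sim <- make_genome(seed = seed)
  g <- sim$genes$FOSL
  fp <- sim$truth$fos_partner
  sp <- spike_rearrangement(
    sim, "FOSL", g$exons$start[4] + offset,
    genomic_interval("chr2", fp$junction, fp$region$end),
    insert = insert)
  list(sim = sp$sim, r = sp$rearrangement, gene = g, fp = fp)
}

test_that("an exonic break truncates the exon exactly at the break", {
  fx <- fos_fusion(offset = 50L)
  ft <- build_fusion_transcript(fx$r, fx$sim$genes, fx$sim$genome,
                                transcript_end = fx$fp$cleavage + 1L)
  five_segs <- ft$segments[seq_len(length(ft$segments) - 1L)]
  last5 <- five_segs[[length(five_segs)]]
  expect_equal(last5$interval$end, fx$gene$exons$start[4] + 50L)
  expect_equal(ft$junction_offset, 520L + 50L)
  # junction sequence equals spliced 5' exons + partner slice
  expect_equal(nchar(ft$sequence),
               ft$junction_offset + nchar(ft$insert) +
                 (fx$fp$cleavage + 1L - fx$fp$junction))
})

test_that("an intronic break exonises the retained intron (donor skipped)", {
  sim <- make_genome(seed = 22)
  g5 <- sim$genes$PPRL
  gb <- sim$genes$FOSBL
  pj <- gb$exons$start[2] + 61L
  sp <- spike_rearrangement(sim, "PPRL", g5$exons$end[2] + 50L,
                            genomic_interval("chr1", pj, gb$body$end),
                            insert = "GCC")
  ft <- build_fusion_transcript(sp$rearrangement, sim$genes, sim$genome,
                                transcript_end = gb$body$end)
  # 5' part = exons 1+2 (420 nt) plus 50 nt of exonised intron
  expect_equal(ft$junction_offset, 420L + 50L)
  # the exonised segment is contiguous genomic sequence through the donor
  last5 <- ft$segments[[length(ft$segments) - 1L]]
  expect_equal(last5$interval$start, g5$exons$start[2])
  expect_equal(last5$interval$end, g5$exons$end[2] + 50L)
  expect_equal(ft$retained_native_len, 420L)
})

test_that("transcript length bookkeeping holds over 100 random fusions", {
  sim <- make_genome(seed = 23)
  g <- sim$genes$FOSL
  set.seed(230)
  for (i in 1:100) {
    bpos <- sample(g$body$start:(g$body$end - 1L), 1L)
    ins <- paste(sample(c("A", "C", "G", "T"), sample(0:6, 1L),
                        replace = TRUE), collapse = "")
    s0 <- sample(1000:30000, 1L)
    r <- rearrangement(break_end("chr1", bpos, "retained-left"),
                       break_end("chr2", s0, "retained-right"),
                       non_template_insert = ins)
    ft <- build_fusion_transcript(r, sim$genes, sim$genome,
                                  transcript_end = s0 + 500L)
    expect_equal(nchar(ft$sequence),
                 sum(vapply(ft$segments, function(s) nchar(s$sequence),
                            integer(1))) + nchar(ins))
  }
})

test_that("re-deriving the transcript matches the simulator contig locally", {
  # with the break at an exon-4 position, the fusion transcript's unspliced
  # tail (truncated exon 4 + partner) is a substring of the tumour contig
  fx <- fos_fusion(seed = 24, offset = 80L)
  ft <- build_fusion_transcript(fx$r, fx$sim$genes, fx$sim$genome,
                                transcript_end = fx$fp$cleavage + 1L)
  sp <- spike_rearrangement(fx$sim, "FOSL", fx$gene$exons$start[4] + 80L,
                            genomic_interval("chr2", fx$fp$junction,
                                             fx$fp$cleavage + 1L))
  tail_seq <- paste0(ft$segments[[4]]$sequence, ft$segments[[5]]$sequence)
  expect_true(grepl(tail_seq, sp$contig, fixed = TRUE))
})

test_that("a TGA insert at an in-frame junction stops at offset 0", {
  fx <- fos_fusion(seed = 25, offset = 51L, insert = "TGA")
  # junction transcript coord 520 + 51 = 571; frame from cds_start 31:
  # (571 - 31) %% 3 == 0, so the insert is the next codon
  ft <- build_fusion_transcript(fx$r, fx$sim$genes, fx$sim$genome,
                                transcript_end = fx$fp$cleavage + 1L)
  ft <- translate_and_classify(ft)
  expect_equal(ft$classification, "TRUNCATING")
  expect_equal(ft$stop_offset_codons, 0L)
})

test_that("classification matches the naive codon-scan oracle on random transcripts", {
  set.seed(250)
  for (i in 1:300) {
    n <- sample(60:600, 1L)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    cds_start <- sample(0:10, 1L)
    junction <- sample((cds_start + 3L):(n - 10L), 1L)
    ft <- structure(list(sequence = seq, cds_start = cds_start,
                         junction_offset = junction,
                         retained_native_len = junction,
                         insert = ""),
                    class = "fusion_transcript")
    got <- translate_and_classify(ft)$classification
    expect_equal(got, naive_classify(seq, cds_start, junction),
                 info = sprintf("case %d", i))
  }
})

test_that("classification ignores 3' padding beyond the stop codon", {
  fx <- fos_fusion(seed = 26, offset = 40L)
  short <- translate_and_classify(build_fusion_transcript(
    fx$r, fx$sim$genes, fx$sim$genome, fx$fp$cleavage + 1L))
  long <- translate_and_classify(build_fusion_transcript(
    fx$r, fx$sim$genes, fx$sim$genome, fx$fp$cleavage + 1500L))
  expect_equal(short$classification, long$classification)
  expect_equal(short$stop_offset_codons, long$stop_offset_codons)
})

test_that("NON_CODING and UNTERMINATED outcomes are reported distinctly", {
  sim <- make_genome(seed = 27)
  g <- sim$genes$FOSL
  # break inside exon 1 before the start codon (cds_start = 31)
  r <- rearrangement(break_end("chr1", g$exons$start[1] + 10L, "retained-left"),
                     break_end("chr2", 30000L, "retained-right"))
  ft <- translate_and_classify(build_fusion_transcript(
    r, sim$genes, sim$genome, 30200L))
  expect_equal(ft$classification, "NON_CODING")

  # stop-free construct: junction into a synthetic stop-free tail
  ft2 <- structure(list(sequence = paste0("ATG", strrep("GCA", 50)),
                        cds_start = 0L, junction_offset = 30L,
                        retained_native_len = 30L, insert = ""),
                   class = "fusion_transcript")
  expect_equal(translate_and_classify(ft2)$classification, "UNTERMINATED")
})

test_that("neither end in a gene is an explicit error", {
  sim <- make_genome(seed = 28)
  r <- rearrangement(break_end("chr1", 100L, "retained-left"),
                     break_end("chr2", 30000L, "retained-right"))
  expect_error(build_fusion_transcript(r, sim$genes, sim$genome, 30500L),
               "not a transcribable fusion")
})

test_that("frame_compatible implements mod-3 arithmetic", {
  expect_true(frame_compatible(300L, 3L, 0L))
  expect_false(frame_compatible(300L, 1L, 0L))
  expect_true(frame_compatible(299L, 1L, 0L))
  expect_true(frame_compatible(300L, 2L, 2L))
})

test_that("regulatory elements not fully retained are reported lost", {
  sim <- make_genome(seed = 29)
  g <- sim$genes$FOSL
  mk_ft <- function(retained) structure(
    list(retained_native_len = retained), class = "fusion_transcript")
  # elements at transcript [760,820) and [900,1000)
  expect_setequal(regulatory_loss(mk_ft(700L), g),
                  c("instability_determinant", "AU_rich_element"))
  expect_length(regulatory_loss(mk_ft(1010L), g), 0L)
  # straddling: retained ends inside the first element
  expect_setequal(regulatory_loss(mk_ft(800L), g),
                  c("instability_determinant", "AU_rich_element"))
})
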