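# polya_detection: normalisation, peak detection, motif scan, cleavage
# calling, segment means

test_that("normalisation divides by the mean count and scales", {
  tr <- coverage_track(genomic_interval("chr2", 0L, 100L), rep(50, 100))
  counts <- data.frame(gene = letters[1:4], count = rep(1000, 4))
  n1 <- normalise_coverage(tr, counts, norm_scale = 1e3)
  expect_equal(n1$values, rep(50, 100))
  # homogeneity: doubling counts halves values
  counts2 <- transform(counts, count = count * 2)
  n2 <- normalise_coverage(tr, counts2, norm_scale = 1e3)
  expect_equal(n2$values, n1$values / 2)
  # inverse transform recovers the raw values exactly
  expect_equal(n1$values / n1$norm_factor, tr$values)
  expect_error(normalise_coverage(tr, data.frame(gene = "a", count = 0)),
               "mean gene count")
})

test_that("detect_peak flags carriers and respects invariances", {
  region <- genomic_interval("chr2", 0L, 100L)
  mk <- function(v) coverage_track(region, rep(v, 100))
  tracks <- list(carrier = mk(50), n1 = mk(0.5), n2 = mk(0.5), n3 = mk(0.5))
  expect_equal(detect_peak(tracks, region, 5), "carrier")

  same <- list(a = mk(3), b = mk(3), c = mk(3))
  expect_length(detect_peak(same, region, 5), 0L)

  # two carriers in a large cohort: exactly those two
  cohort <- c(list(c1 = mk(50), c2 = mk(50)),
              stats::setNames(lapply(1:10, function(i) mk(0)),
                              paste0("n", 1:10)))
  expect_setequal(detect_peak(cohort, region, 5), c("c1", "c2"))

  # invariance under common rescaling
  scaled <- lapply(tracks, function(t) coverage_track(region, t$values * 3))
  expect_equal(detect_peak(scaled, region, 5), "carrier")

  expect_error(detect_peak(tracks["carrier"], region, 5), "at least 2")
})

test_that("motif scanning finds exact, overlapping occurrences", {
  expect_equal(scan_polya_motifs("GGAATAAAGG"), 2L)
  expect_equal(scan_polya_motifs("AATAAATAAA"), c(0L, 4L))
  expect_length(scan_polya_motifs("GGGGGG"), 0L)
})

test_that("cleavage is called at a step drop and matches the brute oracle", {
  params <- fusion_params()
  region <- genomic_interval("chr2", 0L, 600L)
  motif <- 200L
  cleave <- motif + 6L - 1L + 20L   # offset 20
  vals <- c(rep(100, cleave + 1L), rep(0, 600L - cleave - 1L))
  tr <- coverage_track(region, vals)
  call <- call_cleavage_site(tr, motif, params)
  expect_equal(call$cleavage_site, cleave)
  expect_equal(call$offset, 20L)
  expect_gt(call$drop_magnitude, 99)

  orc <- oracle_polya(vals, 0L, motif, params)
  expect_equal(call$cleavage_site, orc$cleavage)
  expect_equal(call$drop_magnitude, orc$drop)

  # uniform coverage: no positive drop anywhere
  flat <- coverage_track(region, rep(7, 600))
  expect_null(call_cleavage_site(flat, motif, params))

  # no motifs: distinct (messaged) none
  expect_message(expect_null(call_cleavage_site(tr, integer(), params)),
                 "no polyA motif")
})

test_that("with two motifs the one at the real drop wins; drop is linear", {
  params <- fusion_params()
  region <- genomic_interval("chr2", 0L, 900L)
  m1 <- 100L; m2 <- 500L
  cleave <- m2 + 6L - 1L + 15L
  vals <- c(rep(60, cleave + 1L), rep(0, 900L - cleave - 1L))
  tr <- coverage_track(region, vals)
  call <- call_cleavage_site(tr, c(m1, m2), params)
  expect_equal(call$motif_site, m2)
  expect_equal(call$cleavage_site, cleave)

  scaled <- call_cleavage_site(coverage_track(region, vals * 4),
                               c(m1, m2), params)
  expect_equal(scaled$cleavage_site, call$cleavage_site)
  expect_equal(scaled$drop_magnitude, 4 * call$drop_magnitude)
})

test_that("call_cleavage_site equals the brute-force maximiser on noisy tracks", {
  params <- fusion_params()
  set.seed(321)
  for (i in 1:25) {
    region <- genomic_interval("chr2", 0L, 800L)
    motifs <- sort(sample(100:600, sample(1:3, 1)))
    vals <- rpois(800, lambda = sample(5:60, 1) *
                    exp(-(seq_len(800)) / sample(200:2000, 1)))
    tr <- coverage_track(region, as.numeric(vals))
    got <- call_cleavage_site(tr, motifs, params)
    orc <- oracle_polya(as.numeric(vals), 0L, motifs, params)
    if (is.null(orc)) {
      expect_null(got)
    } else {
      expect_equal(got$cleavage_site, orc$cleavage)
      expect_equal(got$offset, orc$offset)
      expect_equal(got$drop_magnitude, orc$drop)
    }
  }
})

test_that("segment means cover the mate transcript and equal-length flanks", {
  region <- genomic_interval("chr2", 0L, 300L)
  vals <- c(rep(0, 100), rep(50, 100), rep(0, 100))
  tr <- coverage_track(region, vals)
  sm <- segment_means(tr, 100L, 199L)
  expect_equal(unname(sm), c(0, 50, 0))

  const <- coverage_track(region, rep(4, 300))
  expect_equal(unname(segment_means(const, 120L, 180L)), c(4, 4, 4))

  expect_error(segment_means(tr, 200L, 150L), "3'")
})
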