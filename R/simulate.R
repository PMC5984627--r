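# Deterministic synthetic genomes with known ground truth.
#
# The default world is a toy 2 x 50 kb genome carrying four designed genes:
#   FOSL  - a 4-exon FOS-like gene whose exon 4 holds a 200 bp break window
#           with annotated regulatory elements (instability determinant,
#           AU-rich element) downstream of it;
#   FOSBL - a 4-exon FOSB-like gene used as the coding 3' partner of the
#           in-frame fusion scenario;
#   PPRL  - a 3-exon PPP1R10-like 5' partner whose intron 2 is exonised by
#           an intronic break (splice donor skipped);
#   TSGL  - a generic tumour suppressor for driver-screen tests.
# Chromosome 2 is intergenic partner territory with one planted AATAAA
# signal and a stop cassette at the fusion junction, so the truncating
# read-through transcript and its cleavage site are known exactly.
#
# All generators are deterministic under a fixed seed. AATAAA is scrubbed
# everywhere on the plus strand except where planted: the scrub replaces
# the motif's third base with C, which can never create a stop codon
# (stops contain no C), so designed reading frames survive it.

STOP_CASSETTE <- "TAGATAGATAGA"  # stop codon in all three frames, AATAAA-free

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

nonstop_codons <- function() {
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1L, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_orf_codons <- function(n) {
  paste(sample(nonstop_codons(), n, replace = TRUE), collapse = "")
}

scrub_motif <- function(seq, motif = "AATAAA") {
  repeat {
    hit <- regexpr(motif, seq, fixed = TRUE)[1]
    if (hit == -1L) return(seq)
    substring(seq, hit + 2L, hit + 2L) <- "C"
  }
}

plant <- function(seq, pos0, what) {
  substring(seq, pos0 + 1L, pos0 + nchar(what)) <- what
  seq
}

# Design one gene: transcript with a clean ORF, split into exons with
# random (scrubbed) introns. `intron_special` is an optional list of
# index -> sequence-patch function.
design_gene <- function(exon_lens, intron_lens, cds_start, cds_end,
                        intron_build = NULL) {
  tl <- sum(exon_lens)
  stopifnot(cds_end <= tl, (cds_end - cds_start) %% 3L == 0L)
  n_codons <- (cds_end - cds_start) %/% 3L
  tx <- paste0(
    if (cds_start > 0L) random_dna(cds_start) else "",
    "ATG", random_orf_codons(n_codons - 2L), "TGA",
    if (tl > cds_end) random_dna(tl - cds_end) else "")
  tx <- scrub_motif(tx)
  cuts <- cumsum(exon_lens)
  exon_seqs <- substring(tx, c(1L, cuts[-length(cuts)] + 1L), cuts)
  introns <- lapply(seq_along(intron_lens), function(i) {
    s <- scrub_motif(random_dna(intron_lens[i]))
    if (!is.null(intron_build) && !is.null(intron_build[[as.character(i)]]))
      s <- intron_build[[as.character(i)]](s)
    s
  })
  pieces <- character(0)
  rel <- data.frame(start = integer(), end = integer())
  off <- 0L
  for (i in seq_along(exon_seqs)) {
    rel <- rbind(rel, data.frame(start = off, end = off + exon_lens[i]))
    pieces <- c(pieces, exon_seqs[i])
    off <- off + exon_lens[i]
    if (i <= length(introns)) {
      pieces <- c(pieces, introns[[i]])
      off <- off + intron_lens[i]
    }
  }
  list(seq = paste(pieces, collapse = ""), exons_rel = rel,
       transcript = tx, cds_start = cds_start, cds_end = cds_end)
}

#' Generate a toy genome with designed genes and ground truth
#'
#' Deterministic for a fixed seed: two calls with the same arguments yield
#' byte-identical FASTA and GFF3. See the file-level notes for what each
#' designed gene emulates.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes to place (>= 2; the first four are the
#'   designed FOSL/FOSBL/PPRL/TSGL models, extras are generic two-exon
#'   genes).
#' @param chrom_lengths Named integer vector of chromosome lengths in bp
#'   (each >= 10 kb). Default `c(chr1 = 50000, chr2 = 50000)`.
#' @return A list of class `fusion_sim` with `genome` (DNAStringSet),
#'   `genes` (named list of [gene_model]) and `truth` (partner-region
#'   layout, planted motif and cleavage positions, empty rearrangement
#'   list).
#' @export
make_genome <- function(seed = 1L, n_genes = 4L,
                        chrom_lengths = c(chr1 = 50000L, chr2 = 50000L)) {
  if (any(chrom_lengths < 10000L)) stop("chromosome lengths must be >= 10 kb")
  if (n_genes < 2L) stop("need at least 2 genes")
  if (length(chrom_lengths) < 2L) stop("need at least 2 chromosomes")
  gene_pitch <- 7000L
  if (2000L + n_genes * gene_pitch > chrom_lengths[[1L]])
    stop("chromosome 1 too small to place the requested genes")
  set.seed(seed)
  chr1 <- scrub_motif(random_dna(chrom_lengths[[1L]]))
  chr2 <- scrub_motif(random_dna(chrom_lengths[[2L]]))

  designs <- list(
    FOSL = design_gene(c(150L, 120L, 250L, 600L), c(300L, 300L, 400L),
                       cds_start = 31L, cds_end = 670L),
    FOSBL = design_gene(c(200L, 180L, 150L, 500L), c(250L, 250L, 300L),
                        cds_start = 49L, cds_end = 730L,
                        intron_build = list("2" = function(s)
                          plant(s, 12L, STOP_CASSETTE))),
    # intron 2 of PPRL: first 48 bp are frame-0 stop-free codons and bases
    # 49-50 are CC, so a 50 bp exonisation keeps the frame open and the
    # straddling codon contains a C (never a stop)
    PPRL = design_gene(c(180L, 240L, 300L), c(400L, 350L),
                       cds_start = 60L, cds_end = 540L,
                       intron_build = list("2" = function(s)
                         plant(s, 0L, paste0(random_orf_codons(16L), "CC")))),
    TSGL = design_gene(c(300L, 300L), 500L, cds_start = 20L, cds_end = 500L))
  n_extra <- max(0L, n_genes - 4L)
  for (k in seq_len(n_extra)) {
    designs[[paste0("GEN", k)]] <-
      design_gene(c(200L, 200L), 300L, cds_start = 10L, cds_end = 400L)
  }
  designs <- designs[seq_len(min(n_genes, length(designs)))]

  genes <- list()
  start <- 2000L
  chrom1 <- names(chrom_lengths)[1L]
  for (nm in names(designs)) {
    d <- designs[[nm]]
    glen <- nchar(d$seq)
    chr1 <- plant(chr1, start, d$seq)
    exons <- data.frame(start = d$exons_rel$start + start,
                        end = d$exons_rel$end + start)
    re <- if (nm == "FOSL") {
      data.frame(label = c("instability_determinant", "AU_rich_element"),
                 start = c(760L, 900L), end = c(820L, 1000L),
                 stringsAsFactors = FALSE)
    } else empty_regulatory()
    genes[[nm]] <- gene_model(
      gene_id = nm, name = nm,
      body = genomic_interval(chrom1, start, start + glen, "+"),
      exons = exons, cds_start = d$cds_start, cds_end = d$cds_end,
      regulatory_elements = re)
    start <- start + gene_pitch
  }

  # intergenic partner landscape on chromosome 2: a stop cassette at the
  # junction, one AATAAA signal 150 bp in, cleavage 10-30 bp downstream
  chrom2 <- names(chrom_lengths)[2L]
  junction <- 21000L
  motif <- 21150L
  offset <- sample(10:30, 1L)
  chr2 <- plant(chr2, junction, STOP_CASSETTE)
  chr2 <- plant(chr2, motif, "AATAAA")
  cleavage <- motif + 6L - 1L + offset   # 0-based last transcribed base
  genome <- Biostrings::DNAStringSet(
    stats::setNames(c(chr1, chr2), c(chrom1, chrom2)))
  truth <- list(
    chrom_lengths = chrom_lengths,
    fos_partner = list(
      region = genomic_interval(chrom2, 19000L, 24000L),
      junction = junction, motif = motif, offset = offset,
      cleavage = cleavage, n_motifs = 1L),
    rearrangements = list(),
    true_cleavage_site = integer(), true_frame_class = character(),
    true_ase_ratio = numeric(), true_cn_events = list())
  structure(list(genome = genome, genes = genes, truth = truth,
                 seed = seed),
            class = "fusion_sim")
}

#' Spike a rearrangement into a simulated genome
#'
#' The derived tumour contig is the 5' reference sequence from the gene
#' start to the break, the non-template insert, then the partner sequence.
#' Break positions are half-open bounds: the retained 5' segment is
#' `[gene start, break_pos)` and the retained partner segment starts at the
#' partner interval's start.
#'
#' @param sim A `fusion_sim`.
#' @param gene_id 5' gene carrying the break.
#' @param break_pos 0-based genomic break position inside the gene body.
#' @param partner [genomic_interval] of retained partner sequence (must not
#'   overlap the source gene); its start is the partner-side junction.
#' @param insert Non-template insert sequence (may be `""`).
#' @param sample_id Sample label.
#' @param frame_class Truth classification recorded for this fusion.
#' @param cleavage_site Truth cleavage site recorded for this fusion (NA
#'   when the partner has its own 3' end).
#' @return List with `sim` (truth updated), `rearrangement` and `contig`.
#' @export
spike_rearrangement <- function(sim, gene_id, break_pos, partner,
                                insert = "", sample_id = "tumour1",
                                frame_class = NA_character_,
                                cleavage_site = NA_integer_) {
  g <- sim$genes[[gene_id]]
  if (is.null(g)) stop(sprintf("unknown gene %s", gene_id))
  if (!iv_contains(g$body, break_pos))
    stop("break position outside the named gene")
  if (iv_overlaps(partner, g$body))
    stop("partner region overlaps the source gene")
  r <- rearrangement(
    break_end(g$body$chrom, break_pos, "retained-left"),
    break_end(partner$chrom, partner$start, "retained-right"),
    non_template_insert = insert, sample_id = sample_id)
  contig <- paste0(
    genome_sequence(sim$genome,
                    genomic_interval(g$body$chrom, g$body$start, break_pos)),
    insert,
    genome_sequence(sim$genome, partner))
  sim$truth$rearrangements <- c(sim$truth$rearrangements, list(r))
  sim$truth$true_frame_class <- c(sim$truth$true_frame_class, frame_class)
  sim$truth$true_cleavage_site <- c(sim$truth$true_cleavage_site,
                                    cleavage_site)
  list(sim = sim, rearrangement = r, contig = contig)
}

#' Simulate a per-base RNA coverage track
#'
#' Carrier samples have mean `mean_depth` over the transcribed interval,
#' decaying exponentially to ~0 within 5 bp after the cleavage site;
#' elsewhere (and in non-carrier samples) the mean is `background_depth`.
#' `noise = 0` gives the deterministic idealised track (a hard cliff at
#' the cleavage site); `noise > 0` draws Poisson counts around the decaying
#' mean.
#'
#' @param region [genomic_interval] the track spans.
#' @param transcribed [genomic_interval] of the aberrant transcript on this
#'   chromosome (junction to cleavage site, half-open), or `NULL` for a
#'   background-only sample.
#' @param mean_depth Mean read depth over the transcript.
#' @param noise 0 for the noiseless limit, > 0 for Poisson counts.
#' @param seed Optional RNG seed.
#' @param background_depth Mean depth outside the transcript; default 0.
#' @param decay_rate Exponential decay per bp past the cleavage site.
#' @return A raw [coverage_track].
#' @export
simulate_coverage <- function(region, transcribed = NULL, mean_depth = 50,
                              noise = 1, seed = NULL, background_depth = 0,
                              decay_rate = 1.2) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- iv_width(region)
  lam <- rep(background_depth, n)
  if (!is.null(transcribed)) {
    stopifnot(transcribed$chrom == region$chrom)
    i1 <- transcribed$start - region$start + 1L
    i2 <- transcribed$end - region$start
    lam[i1:i2] <- mean_depth
    if (noise > 0) {
      for (k in 1:5) {
        idx <- i2 + k
        if (idx <= n) lam[idx] <- max(lam[idx], mean_depth * exp(-decay_rate * k))
      }
    }
  }
  vals <- if (noise > 0) stats::rpois(n, lam) else lam
  coverage_track(region, vals)
}

#' Simulate per-read pileup records at heterozygous SNPs
#'
#' Alt counts are Binomial(depth, ase_ratio) per SNP; base and mapping
#' qualities are emitted above the default filters.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param depth Reads per SNP.
#' @param ase_ratio Expected alt fraction in \[0, 1\].
#' @param seed Optional RNG seed.
#' @return data.frame of pileup records (see [read_pileup()]).
#' @export
simulate_pileup <- function(snps, depth = 50L, ase_ratio = 0.5,
                            seed = NULL) {
  if (ase_ratio < 0 || ase_ratio > 1) stop("ase_ratio must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    na <- stats::rbinom(1L, depth, ase_ratio)
    data.frame(chrom = snps$chrom[i], pos = snps$pos[i],
               base = c(rep(snps$alt[i], na), rep(snps$ref[i], depth - na)),
               base_qual = 37L, map_qual = 60L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample heterozygous SNPs inside a gene
#'
#' @param sim A `fusion_sim`.
#' @param gene_id Gene to place SNPs in.
#' @param n Number of SNPs.
#' @param seed Optional RNG seed.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gt`.
#' @export
simulate_het_snps <- function(sim, gene_id, n = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- sim$genes[[gene_id]]
  pos <- sort(sample(g$body$start:(g$body$end - 1L), n))
  ref <- vapply(pos, function(p)
    genome_sequence(sim$genome,
                    genomic_interval(g$body$chrom, p, p + 1L)), character(1))
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  data.frame(chrom = g$body$chrom, pos = pos, ref = ref, alt = unname(alt),
             gt = "0/1", stringsAsFactors = FALSE)
}

#' Simulate a copy-number profile with optional spiked events
#'
#' The background is diploid (total 2, minor 1) over every chromosome;
#' spiked events replace their span.
#'
#' @param sim A `fusion_sim`.
#' @param events List of lists with fields `interval` ([genomic_interval]),
#'   `total_cn`, `minor_cn`.
#' @return data.frame of segments (see [read_cn_segments()]).
#' @export
simulate_cn <- function(sim, events = list()) {
  segs <- list()
  for (chrom in names(sim$truth$chrom_lengths)) {
    len <- sim$truth$chrom_lengths[[chrom]]
    ev <- Filter(function(e) e$interval$chrom == chrom, events)
    ev <- ev[order(vapply(ev, function(e) e$interval$start, numeric(1)))]
    cur <- 0L
    for (e in ev) {
      if (e$interval$start > cur)
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = chrom, start = cur, end = e$interval$start,
          total_cn = 2L, minor_cn = 1L)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = e$interval$start, end = e$interval$end,
        total_cn = e$total_cn, minor_cn = e$minor_cn)
      cur <- e$interval$end
    }
    if (cur < len)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = cur, end = len, total_cn = 2L, minor_cn = 1L)
  }
  do.call(rbind, segs)
}

#' Simulate junction-supporting read segments
#'
#' Emits `n_split` split reads whose two segments abut the two break ends,
#' `n_pairs` discordant pairs whose mates flank them on the retained
#' sides, and `n_decoy` split reads supporting an unrelated junction 10 kb
#' away.
#'
#' @param r A [rearrangement].
#' @param n_split,n_pairs,n_decoy Counts to emit.
#' @param read_len Segment length.
#' @return data.frame usable by [count_supporting_reads()].
#' @export
simulate_reads <- function(r, n_split = 3L, n_pairs = 2L, n_decoy = 0L,
                           read_len = 100L) {
  side <- function(be, role) {
    if (be$orientation == "retained-left") {
      if (role == "split") c(be$pos - read_len, be$pos)
      else c(be$pos - 300L, be$pos - 200L)
    } else {
      if (role == "split") c(be$pos, be$pos + read_len)
      else c(be$pos + 200L, be$pos + 300L)
    }
  }
  mk <- function(qname, type, s1, s2, c1, c2) {
    data.frame(qname = qname, type = type,
               chrom1 = c1, start1 = s1[1], end1 = s1[2],
               chrom2 = c2, start2 = s2[1], end2 = s2[2],
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(n_split))
    rows[[length(rows) + 1L]] <- mk(sprintf("split%d", i), "split",
                                    side(r$end1, "split"),
                                    side(r$end2, "split"),
                                    r$end1$chrom, r$end2$chrom)
  for (i in seq_len(n_pairs))
    rows[[length(rows) + 1L]] <- mk(sprintf("pair%d", i), "pair",
                                    side(r$end1, "pair"),
                                    side(r$end2, "pair"),
                                    r$end1$chrom, r$end2$chrom)
  for (i in seq_len(n_decoy)) {
    fake1 <- break_end(r$end1$chrom, r$end1$pos + 10000L, r$end1$orientation)
    fake2 <- break_end(r$end2$chrom, r$end2$pos + 10000L, r$end2$orientation)
    rows[[length(rows) + 1L]] <- mk(sprintf("decoy%d", i), "split",
                                    side(fake1, "split"),
                                    side(fake2, "split"),
                                    fake1$chrom, fake2$chrom)
  }
  if (!length(rows))
    return(data.frame(qname = character(), type = character(),
                      chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer()))
  do.call(rbind, rows)
}

derive_seed <- function(seed, k) (as.integer(seed) * 1000L + k) %% 2147483647L

#' Simulate a complete analysis scenario
#'
#' Scenarios:
#' * `"fos-like"`: exonic break in the 200 bp window of FOSL exon 4, no
#'   insert, intergenic partner with a planted stop cassette and AATAAA;
#'   truth class TRUNCATING with a known cleavage site.
#' * `"fosb-like"`: break 50 bp into PPRL intron 2 (exonised, donor
#'   skipped), 3 nt non-template insert, junction into the FOSBL coding
#'   exon at a frame-compatible phase; truth class IN_FRAME_FUSION.
#' * `"negative"`: no rearrangement; background-only data.
#'
#' DNA calls are emitted exactly; RNA calls are jittered by up to
#' `rna_jitter` bp. One DNA-only and one RNA-only decoy call are added so
#' reconciliation has something to reject.
#'
#' @param scenario One of `"fos-like"`, `"fosb-like"`, `"negative"`.
#' @param seed Integer seed controlling every random choice.
#' @param out_dir Optional directory; when given, all interchange files
#'   (FASTA, GFF3, BEDPE x2, bedGraph per sample, counts, VCF, pileup,
#'   copy-number and cancer-gene TSVs, truth JSON) are written there.
#' @param mean_depth Carrier coverage depth; default 50.
#' @param noise 0 = noiseless, > 0 = Poisson; default 1.
#' @param n_background Number of non-carrier samples; default 3.
#' @param ase_ratio Alt fraction at FOSL het SNPs in the carrier; default
#'   0.9 (allelic imbalance expected of a mono-allelic rearrangement).
#' @param rna_jitter Max RNA break-point offset in bp; default 3.
#' @return A list with the `fusion_sim`, the rearrangement lists
#'   (`dna`, `rna`), coverage `tracks`, `gene_counts`, `snps`, `pileup`,
#'   `cn`, `cancer_genes`, `truth` and (if written) `files`.
#' @export
simulate_scenario <- function(scenario = c("fos-like", "fosb-like",
                                           "negative"),
                              seed = 1L, out_dir = NULL, mean_depth = 50,
                              noise = 1, n_background = 3L,
                              ase_ratio = 0.9, rna_jitter = 3L) {
  scenario <- match.arg(scenario)
  sim <- make_genome(seed = derive_seed(seed, 1L))
  set.seed(derive_seed(seed, 2L))
  dna <- list(); rna <- list()
  carrier <- "tumour1"
  fusion <- NULL

  if (scenario == "fos-like") {
    g <- sim$genes$FOSL
    exon4 <- g$exons[4L, ]
    break_pos <- exon4$start + sample(30:229, 1L)
    fp <- sim$truth$fos_partner
    partner <- genomic_interval(fp$region$chrom, fp$junction, fp$region$end)
    sp <- spike_rearrangement(sim, "FOSL", break_pos, partner,
                              insert = "", sample_id = carrier,
                              frame_class = "TRUNCATING",
                              cleavage_site = fp$cleavage)
    sim <- sp$sim; fusion <- sp$rearrangement
  } else if (scenario == "fosb-like") {
    g5 <- sim$genes$PPRL
    break_pos <- g5$exons$end[2L] + 50L
    gb <- sim$genes$FOSBL
    # junction at FOSBL transcript coordinate 261 (CDS offset 212, phase 2):
    # frame-compatible with 360 + 50 exonised + 3 insert upstream nt
    pj <- gb$exons$start[2L] + (261L - 200L)
    partner <- genomic_interval(gb$body$chrom, pj, gb$body$end)
    sp <- spike_rearrangement(sim, "PPRL", break_pos, partner,
                              insert = "GCC", sample_id = carrier,
                              frame_class = "IN_FRAME_FUSION")
    sim <- sp$sim; fusion <- sp$rearrangement
  }

  if (!is.null(fusion)) {
    dna <- list(fusion)
    jit <- function(be) break_end(
      be$chrom, be$pos + sample(-rna_jitter:rna_jitter, 1L), be$orientation)
    rna <- list(rearrangement(jit(fusion$end1), jit(fusion$end2),
                              fusion$non_template_insert,
                              sample_id = carrier, evidence = "RNA"))
    # decoys: a DNA-only call and an RNA-only call far from the fusion
    dna <- c(dna, list(rearrangement(
      break_end(fusion$end1$chrom, 40000L, "retained-left"),
      break_end(fusion$end2$chrom, 40000L, "retained-right"),
      sample_id = carrier)))
    rna <- c(rna, list(rearrangement(
      break_end(fusion$end1$chrom, 45000L, "retained-left"),
      break_end(fusion$end2$chrom, 45000L, "retained-right"),
      sample_id = carrier, evidence = "RNA")))
  }

  # coverage over the intergenic partner region (the polyA search space)
  fp <- sim$truth$fos_partner
  samples <- c(carrier, paste0("normal", seq_len(n_background)))
  transcribed <- if (scenario == "fos-like")
    genomic_interval(fp$region$chrom, fp$junction, fp$cleavage + 1L)
  else NULL
  tracks <- stats::setNames(lapply(seq_along(samples), function(i) {
    simulate_coverage(fp$region,
                      transcribed = if (i == 1L) transcribed else NULL,
                      mean_depth = mean_depth, noise = noise,
                      seed = derive_seed(seed, 10L + i))
  }), samples)

  gene_counts <- data.frame(
    gene = names(sim$genes),
    count = c(2000L, 1500L, 1000L, 500L)[seq_along(sim$genes)])

  snps <- simulate_het_snps(sim, "FOSL", n = 5L, seed = derive_seed(seed, 20L))
  pileup <- simulate_pileup(snps, depth = mean_depth,
                            ase_ratio = if (scenario == "negative") 0.5
                                        else ase_ratio,
                            seed = derive_seed(seed, 21L))
  cn <- simulate_cn(sim)
  cancer_genes <- data.frame(gene = "TSGL", role = "TSG",
                             stringsAsFactors = FALSE)

  out <- list(sim = sim, scenario = scenario, carrier = carrier,
              sample_id = carrier,
              dna = dna, rna = rna, tracks = tracks,
              gene_counts = gene_counts, snps = snps, pileup = pileup,
              cn = cn, cancer_genes = cancer_genes, truth = sim$truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(out_dir, x)
    Biostrings::writeXStringSet(sim$genome, f("genome.fa"))
    write_annotation(sim$genes, f("annotation.gff3"))
    write_bedpe(dna, f("dna.bedpe"))
    write_bedpe(rna, f("rna.bedpe"))
    for (s in samples)
      write_coverage(tracks[[s]], f(sprintf("coverage_%s.bedgraph", s)))
    write_gene_counts(gene_counts, f("counts.tsv"))
    write_genotype_vcf(snps, f("genotypes.vcf"))
    write_pileup(pileup, f("pileup.tsv"))
    write_cn_segments(cn, f("cn.tsv"))
    utils::write.table(cancer_genes, f("cancer_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth_json <- list(
      scenario = scenario,
      fos_partner = list(junction = fp$junction, motif = fp$motif,
                         offset = fp$offset, cleavage = fp$cleavage),
      true_frame_class = sim$truth$true_frame_class,
      true_cleavage_site = sim$truth$true_cleavage_site)
    jsonlite::write_json(truth_json, f("truth.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    out$files <- list(dir = out_dir)
  }
  out
}
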