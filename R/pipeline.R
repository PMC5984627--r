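# End-to-end orchestration: annotate -> reconcile -> fusion -> polyA ->
# ASE -> drivers, with graceful degradation (a missing optional input
# yields a QC flag, not a crash).

#' Assemble pipeline inputs from a directory of interchange files
#'
#' Expects the file layout written by [simulate_scenario()]: `genome.fa`,
#' `annotation.gff3`, `dna.bedpe`, `rna.bedpe`, `coverage_<sample>.bedgraph`,
#' `counts.tsv`, `genotypes.vcf`, `pileup.tsv`, `cn.tsv`,
#' `cancer_genes.tsv`. Missing optional files come back `NULL`.
#'
#' @param dir Directory path.
#' @param sample_id Carrier sample id; default `"tumour1"`.
#' @return A named list of in-memory inputs for [run_pipeline()].
#' @export
pipeline_inputs_from_dir <- function(dir, sample_id = "tumour1") {
  need <- function(x) {
    p <- file.path(dir, x)
    if (!file.exists(p)) stop(sprintf("missing mandatory input %s", x))
    p
  }
  opt <- function(x) {
    p <- file.path(dir, x)
    if (file.exists(p)) p else NULL
  }
  genome <- Biostrings::readDNAStringSet(need("genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  covs <- list.files(dir, pattern = "^coverage_.*\\.bedgraph$",
                     full.names = TRUE)
  tracks <- if (length(covs)) {
    stats::setNames(lapply(covs, read_coverage),
                    sub("^coverage_(.*)\\.bedgraph$", "\\1", basename(covs)))
  } else NULL
  gc_path <- opt("counts.tsv")
  pu_path <- opt("pileup.tsv")
  gt_path <- opt("genotypes.vcf")
  cn_path <- opt("cn.tsv")
  cg_path <- opt("cancer_genes.tsv")
  list(
    sample_id = sample_id,
    genome = genome,
    genes = read_annotation(need("annotation.gff3")),
    dna = read_bedpe(need("dna.bedpe"), sample_id, "DNA"),
    rna = read_bedpe(need("rna.bedpe"), sample_id, "RNA"),
    tracks = tracks,
    gene_counts = if (!is.null(gc_path)) read_gene_counts(gc_path),
    genotypes = if (!is.null(gt_path)) read_genotype_vcf(gt_path),
    pileup = if (!is.null(pu_path)) read_pileup(pu_path),
    cn = if (!is.null(cn_path)) read_cn_segments(cn_path),
    cancer_genes = if (!is.null(cg_path)) read_cancer_genes(cg_path),
    variants = NULL)
}

mirror_pos <- function(pos, region) region$start + region$end - 1L - pos

# PolyA calling for one reconciled rearrangement's partner side, in the
# predicted transcription orientation (minus-orientation partners are
# handled by mirroring the track and mapping positions back).
partner_polya <- function(r, pick, genome, track, params) {
  pe <- r[[pick$other]]
  region <- track$region
  if (pe$orientation == "retained-right") {
    hi <- region$end
    seq <- genome_sequence(genome, genomic_interval(pe$chrom, pe$pos, hi))
    motifs <- pe$pos + scan_polya_motifs(seq, params$polya_motif)
    call <- call_cleavage_site(track, motifs, params)
    list(call = call, junction = pe$pos, strand = "+")
  } else {
    mtrack <- coverage_track(region, rev(track$values), track$norm_factor)
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      genome_sequence(genome, genomic_interval(pe$chrom, region$start, pe$pos)))))
    jm <- mirror_pos(pe$pos - 1L, region)
    motifs <- jm + scan_polya_motifs(seq, params$polya_motif)
    call <- call_cleavage_site(mtrack, motifs, params)
    if (!is.null(call)) {
      call$cleavage_site <- mirror_pos(call$cleavage_site, region)
      call$motif_site <- mirror_pos(call$motif_site + nchar(params$polya_motif) - 1L,
                                    region)
    }
    list(call = call, junction = pe$pos - 1L, strand = "-")
  }
}

#' Run the full characterisation pipeline for one sample
#'
#' Stages, in dependency order: break-end annotation, DNA/RNA
#' reconciliation, fusion-transcript reconstruction and classification,
#' cryptic polyA calling on non-exonic partner regions, allele-specific
#' expression, driver screening, QC (mono-allelic check). Optional inputs
#' (`tracks`, `gene_counts`, `genotypes`, `pileup`, `cn`, `cancer_genes`,
#' `variants`) may be `NULL`; the affected stage is skipped with a QC
#' flag.
#'
#' @param inputs Named list as produced by [pipeline_inputs_from_dir()] or
#'   [simulate_scenario()] (fields `sample_id`, `genome` or `sim`,
#'   `genes`, `dna`, `rna`, optional `tracks`, `gene_counts`,
#'   `genotypes`/`snps`, `pileup`, `cn`, `cancer_genes`, `variants`).
#' @param params A [fusion_params].
#' @param transcript_extension How far past the partner junction the
#'   provisional transcript extends for translation, bp; classification is
#'   invariant to extra 3' padding. Default 1500.
#' @return A list of class `sample_report`.
#' @export
run_pipeline <- function(inputs, params = fusion_params(),
                         transcript_extension = 1500L) {
  if (!is.null(inputs$sim)) {
    inputs$genome <- inputs$sim$genome
    inputs$genes <- inputs$sim$genes
  }
  for (f in c("genome", "genes", "dna", "rna"))
    if (is.null(inputs[[f]])) stop(sprintf("missing mandatory input '%s'", f))
  genes <- inputs$genes
  genome <- inputs$genome
  qc <- character()
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

  annotate_all <- function(calls) lapply(calls, function(r) {
    list(rearrangement = r,
         context1 = annotate_breakend(r$end1, genes),
         context2 = annotate_breakend(r$end2, genes))
  })
  reconciled <- reconcile(inputs$dna, inputs$rna,
                          slack = params$reconciliation_slack)

  # normalised coverage, shared by peak detection and polyA calling
  ntracks <- NULL
  if (!is.null(inputs$tracks) && !is.null(inputs$gene_counts)) {
    ntracks <- lapply(inputs$tracks, normalise_coverage,
                      gene_counts = inputs$gene_counts,
                      norm_scale = params$norm_scale)
  } else if (!is.null(inputs$tracks)) {
    qc <- c(qc, "no_gene_counts_coverage_unnormalised")
  } else {
    qc <- c(qc, "no_coverage_provided")
  }

  fusions <- list(); polya <- list()
  fusion_genes <- character()
  for (r in reconciled) {
    pick <- pick_five_prime(r, genes)
    if (is.null(pick)) { qc <- c(qc, "unreconstructable_fusion"); next }
    fusion_genes <- c(fusion_genes, pick$gene$gene_id)
    pe <- r[[pick$other]]
    tend <- if (pe$orientation == "retained-right")
      min(pe$pos + transcript_extension, chrom_lengths[[pe$chrom]])
    else max(pe$pos - transcript_extension, 0L)
    ft <- build_fusion_transcript(r, genes, genome, tend)
    ft <- translate_and_classify(ft, params$stop_proximity_codons)
    lost <- regulatory_loss(ft, pick$gene)
    fusions[[length(fusions) + 1L]] <- list(
      gene_id = pick$gene$gene_id,
      break_context = ft$break_context,
      classification = ft$classification,
      stop_offset_codons = ft$stop_offset_codons,
      insert_length = nchar(ft$insert),
      lost_elements = lost)

    pctx <- annotate_breakend(pe, genes)
    if (pctx$category != "EXONIC" && !is.null(ntracks)) {
      carrier_track <- ntracks[[inputs$sample_id]]
      if (is.null(carrier_track)) {
        qc <- c(qc, "carrier_track_missing")
      } else if (pe$chrom != carrier_track$region$chrom ||
                 !iv_contains(carrier_track$region, pe$pos)) {
        qc <- c(qc, "partner_region_not_covered")
      } else {
        peak_region <- if (pe$orientation == "retained-right")
          genomic_interval(pe$chrom, pe$pos,
                           min(pe$pos + 200L, carrier_track$region$end))
        else genomic_interval(pe$chrom,
                              max(pe$pos - 200L, carrier_track$region$start),
                              pe$pos)
        peak_samples <- if (length(ntracks) >= 2L)
          detect_peak(ntracks, peak_region,
                      fold_threshold = params$peak_fold_threshold)
        else { qc <- c(qc, "single_sample_no_peak_test"); inputs$sample_id }
        pa <- partner_polya(r, pick, genome, carrier_track, params)
        sm <- if (!is.null(pa$call)) {
          lo <- min(pa$junction, pa$call$cleavage_site)
          hi <- max(pa$junction, pa$call$cleavage_site)
          segment_means(carrier_track, lo, hi)
        }
        polya[[length(polya) + 1L]] <- list(
          gene_id = pick$gene$gene_id,
          peak_samples = peak_samples,
          call = pa$call, segment_means = sm)
      }
    }
  }

  ase <- NULL
  if (!is.null(inputs$genotypes) || !is.null(inputs$snps)) {
    snps <- if (!is.null(inputs$snps)) inputs$snps
    else {
      target <- if (length(fusion_genes)) genes[unique(fusion_genes)] else genes
      select_het_snps(inputs$genotypes, lapply(target, function(g) g$body))
    }
    if (!is.null(inputs$pileup) && nrow(snps)) {
      ase <- test_imbalance(count_alleles(
        inputs$pileup, snps,
        min_base_qual = params$min_base_qual,
        min_map_qual = params$min_map_qual))
      if (any(ase$low_coverage)) qc <- c(qc, "ase_snp_low_coverage")
    } else {
      qc <- c(qc, "no_pileup_ase_skipped")
    }
  } else {
    qc <- c(qc, "no_genotypes_ase_skipped")
  }

  drivers <- empty_driver_calls()
  if (!is.null(inputs$cancer_genes)) {
    if (!is.null(inputs$variants))
      drivers <- rbind(drivers,
                       screen_small_variants(inputs$variants,
                                             inputs$cancer_genes))
    if (!is.null(inputs$cn))
      drivers <- rbind(drivers,
                       screen_cnv(inputs$cn, genes, inputs$cancer_genes,
                                  params))
    drivers <- rbind(drivers,
                     screen_sv(reconciled, genes, inputs$cancer_genes))
  } else {
    qc <- c(qc, "no_cancer_gene_list_driver_screen_skipped")
  }

  mono <- check_monoallelic(reconciled, genes,
                            slack = params$reconciliation_slack)
  if (any(mono$flagged)) qc <- c(qc, "multiple_breakpoints_in_gene")

  structure(list(
    sample_id = inputs$sample_id,
    rearrangements = annotate_all(reconciled),
    fusions = fusions,
    polya = polya,
    ase = ase,
    drivers = drivers,
    monoallelic = mono,
    qc_flags = unique(qc),
    params = unclass(params)),
    class = "sample_report")
}

#' Write a sample report as JSON
#'
#' Stable field ordering and fixed numeric formatting, so identical runs
#' produce byte-identical reports.
#'
#' @param report A `sample_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_report <- function(report, path) {
  simplify <- function(x) {
    if (inherits(x, c("rearrangement", "break_end", "genomic_interval",
                      "polya_call")))
      return(lapply(unclass(x), simplify))
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  jsonlite::write_json(simplify(unclass(report)), path, auto_unbox = TRUE,
                       digits = 6, pretty = TRUE, na = "null")
  invisible(path)
}

#' Cohort summary: per-gene positives and the combined positive fraction
#'
#' A sample is positive for a gene when it carries at least one reconciled
#' rearrangement there. The combined positive fraction is the sum of
#' per-gene positive counts over the cohort size, reported as a percentage
#' rounded to the nearest integer (half away from zero).
#'
#' @param x Either a named integer vector of per-gene positive sample
#'   counts, or a list of `sample_report`s (counts are then derived).
#' @param cohort_size Total number of samples assayed.
#' @return A list with `per_gene` (named counts), `cohort_size`,
#'   `combined_fraction` and `combined_percent`.
#' @export
summarise_cohort <- function(x, cohort_size) {
  counts <- if (is.numeric(x)) {
    x
  } else {
    tab <- list()
    for (rpt in x) {
      gs <- unique(unlist(lapply(rpt$fusions, function(f) f$gene_id)))
      for (g in gs) tab[[g]] <- c(tab[[g]], rpt$sample_id)
    }
    vapply(tab, function(s) length(unique(s)), integer(1))
  }
  if (cohort_size < 1L) stop("cohort size must be >= 1")
  frac <- sum(counts) / cohort_size
  list(per_gene = counts, cohort_size = as.integer(cohort_size),
       combined_fraction = frac,
       combined_percent = round_half_away(100 * frac))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
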