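# Allele-specific expression at heterozygous SNPs: the mono-allelic
# corollary of a one-allele rearrangement is allelic imbalance in RNA.

#' Select heterozygous SNVs inside target gene bodies
#'
#' @param genotypes data.frame as returned by [read_genotype_vcf()].
#' @param gene_regions List of [genomic_interval] (e.g. gene bodies).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt` for
#'   biallelic heterozygous SNVs falling in a target region.
#' @export
select_het_snps <- function(genotypes, gene_regions) {
  het <- genotypes$gt %in% c("0/1", "0|1", "1|0")
  snv <- genotypes$is_snv
  in_region <- vapply(seq_len(nrow(genotypes)), function(i) {
    any(vapply(gene_regions, function(iv) {
      iv$chrom == genotypes$chrom[i] && iv_contains(iv, genotypes$pos[i])
    }, logical(1)))
  }, logical(1))
  out <- genotypes[het & snv & in_region, c("chrom", "pos", "ref", "alt")]
  rownames(out) <- NULL
  out
}

#' Count ref/alt/other alleles at SNPs from pileup records
#'
#' Reads failing either quality threshold are excluded; remaining base
#' calls are partitioned into reference, alternate and other. A SNP with
#' no covering reads yields a zero record flagged low-coverage.
#'
#' @param pileup data.frame with columns `chrom`, `pos` (0-based), `base`,
#'   `base_qual`, `map_qual` (one row per read observation).
#' @param snps data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param min_base_qual,min_map_qual Quality filters; defaults 20, 20.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, `other_count`, `low_coverage`.
#' @export
count_alleles <- function(pileup, snps, min_base_qual = 20L,
                          min_map_qual = 20L) {
  keep <- pileup$base_qual >= min_base_qual & pileup$map_qual >= min_map_qual
  pp <- pileup[keep, , drop = FALSE]
  out <- snps
  out$ref_count <- out$alt_count <- out$other_count <- 0L
  for (i in seq_len(nrow(snps))) {
    b <- pp$base[pp$chrom == snps$chrom[i] & pp$pos == snps$pos[i]]
    out$ref_count[i] <- sum(b == snps$ref[i])
    out$alt_count[i] <- sum(b == snps$alt[i])
    out$other_count[i] <- sum(b != snps$ref[i] & b != snps$alt[i])
  }
  out$low_coverage <- (out$ref_count + out$alt_count + out$other_count) == 0L
  out
}

#' Test allelic imbalance at each SNP
#'
#' Two-sided exact binomial test of the alt fraction against 0.5 on the
#' informative (ref + alt) reads, Benjamini-Hochberg adjusted across all
#' SNPs in the run. SNPs with zero informative reads get `NA` and a flag.
#'
#' @param counts data.frame from [count_alleles()].
#' @return `counts` with columns `imbalance_p`, `imbalance_q`,
#'   `untestable` appended.
#' @export
test_imbalance <- function(counts) {
  n <- counts$ref_count + counts$alt_count
  p <- rep(NA_real_, nrow(counts))
  testable <- n >= 1L
  p[testable] <- vapply(which(testable), function(i) {
    stats::binom.test(counts$alt_count[i], n[i], p = 0.5,
                      alternative = "two.sided")$p.value
  }, numeric(1))
  counts$imbalance_p <- p
  counts$imbalance_q <- NA_real_
  counts$imbalance_q[testable] <- stats::p.adjust(p[testable], method = "BH")
  counts$untestable <- !testable
  counts
}
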