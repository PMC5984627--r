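# VCF 4.2 interchange. Reading uses VariantAnnotation; the simulator's
# writers emit minimal single-sample VCFs by hand (text format, fixed
# header), which readVcf parses back.

vcf_header_lines <- function(info_lines = character(), sample = "SAMPLE") {
  c("##fileformat=VCFv4.2",
    info_lines,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}

#' Write a genotype VCF of SNVs
#'
#' @param snps data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `gt` (e.g. "0/1").
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(snps, path, sample = "NORMAL") {
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  snps$chrom, snps$pos + 1L,
                  paste0("snp", seq_len(nrow(snps))),
                  snps$ref, snps$alt, snps$gt)
  writeLines(c(vcf_header_lines(sample = sample), rows), path)
  invisible(path)
}

#' Write an annotated small-variant VCF
#'
#' Consequence annotation is an input to the driver screen, not something
#' this package computes; it travels in INFO fields `GENE`, `CSQ`,
#' `DELETERIOUS` (flag) and `HOTSPOT` (flag).
#'
#' @param variants data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `gene`, `csq`, `deleterious` (logical), `hotspot` (logical).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, path) {
  info_lines <- c(
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=DELETERIOUS,Number=0,Type=Flag,Description=\"Annotated functionally deleterious\">",
    "##INFO=<ID=HOTSPOT,Number=0,Type=Flag,Description=\"Previously reported hotspot\">")
  info <- vapply(seq_len(nrow(variants)), function(i) {
    f <- c(sprintf("GENE=%s", variants$gene[i]),
           sprintf("CSQ=%s", variants$csq[i]),
           if (isTRUE(variants$deleterious[i])) "DELETERIOUS",
           if (isTRUE(variants$hotspot[i])) "HOTSPOT")
    paste(f, collapse = ";")
  }, character(1))
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t0/1",
                  variants$chrom, variants$pos + 1L,
                  paste0("var", seq_len(nrow(variants))),
                  variants$ref, variants$alt, info)
  writeLines(c(vcf_header_lines(info_lines), rows), path)
  invisible(path)
}

#' Read annotated small variants for the driver screen
#'
#' @param path VCF with INFO fields `GENE`, `CSQ` and flags `DELETERIOUS`,
#'   `HOTSPOT` (see [write_annotated_vcf()]).
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `gene`, `csq`, `deleterious`, `hotspot`.
#' @export
read_annotated_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "toy")
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alt <- vapply(seq_along(rr), function(i)
    as.character(VariantAnnotation::alt(vcf)[[i]][1]), character(1))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    gene = as.character(info$GENE),
    csq = as.character(info$CSQ),
    deleterious = as.logical(info$DELETERIOUS),
    hotspot = as.logical(info$HOTSPOT),
    stringsAsFactors = FALSE)
}

#' Read a genotype VCF into a variant table
#'
#' @param path Single-sample VCF with a GT field.
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`
#'   (first alternate), `gt`, plus `is_snv` (both alleles single bases).
#' @export
read_genotype_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "toy")
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  alt <- vapply(seq_along(rr), function(i) {
    a <- VariantAnnotation::alt(vcf)[[i]]
    if (length(a)) as.character(a[1]) else NA_character_
  }, character(1))
  ref <- as.character(VariantAnnotation::ref(vcf))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = ref, alt = alt, gt = unname(gt),
    is_snv = nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L,
    stringsAsFactors = FALSE)
}
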