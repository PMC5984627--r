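# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check (plain string/arithmetic R, no Biostrings).

# -- toy gene on a literal chromosome --------------------------------------

toy_genome <- function(seed = 101L, len = 6000L) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(chrT = paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
}

# gene body (1000,2000), exons [(1000,1200), (1800,2000)]
toy_gene <- function(strand = "+") {
  ex <- data.frame(start = c(1000L, 1800L), end = c(1200L, 2000L))
  if (strand == "-") ex <- ex[2:1, ]
  gene_model("toy1", "TOY1",
             genomic_interval("chrT", 1000L, 2000L, strand),
             ex, cds_start = 30L, cds_end = 330L)
}

# -- independent classification oracle: naive 3-mer scan -------------------

naive_classify <- function(seq, cds_start, junction, prox = 10L) {
  if (is.na(cds_start) || cds_start >= junction) return("NON_CODING")
  stops <- c("TAA", "TAG", "TGA")
  i <- cds_start
  while (i + 3L <= nchar(seq)) {
    if (substring(seq, i + 1L, i + 3L) %in% stops) {
      off <- floor((i - junction) / 3)
      return(if (off <= prox) "TRUNCATING" else "IN_FRAME_FUSION")
    }
    i <- i + 3L
  }
  "UNTERMINATED"
}

# -- independent break-end annotation oracle -------------------------------

oracle_annotate <- function(chrom, pos, genes) {
  for (g in genes) {
    if (g$body$chrom != chrom) next
    if (pos >= g$body$start && pos < g$body$end) {
      ex <- g$exons
      inx <- which(pos >= ex$start & pos < ex$end)
      if (length(inx)) return("EXONIC")
      return("INTRONIC")
    }
  }
  "INTERGENIC"
}

# -- independent exhaustive polyA-drop maximiser ---------------------------

oracle_polya <- function(values, region_start, motifs, params) {
  w <- params$drop_window / 2
  n <- length(values)
  best <- NULL
  for (m in sort(motifs)) {
    me <- m + nchar(params$polya_motif)
    for (off in params$cleavage_offset_min:params$cleavage_offset_max) {
      cpos <- me - 1 + off
      ci <- cpos - region_start + 1
      if (ci < 1 || ci > n) next
      left <- values[max(1, ci - w + 1):ci]
      right <- if (ci + 1 <= n) values[(ci + 1):min(n, ci + w)] else numeric()
      d <- mean(left) - (if (length(right)) mean(right) else 0)
      if (is.null(best) || d > best$drop) {
        best <- list(cleavage = cpos, motif = m, offset = off, drop = d)
      }
    }
  }
  if (!is.null(best) && best$drop <= 0) best <- NULL
  best
}

# -- brute-force all-pairs DNA/RNA matcher ---------------------------------

oracle_reconcile <- function(dna, rna, slack) {
  keep <- logical(length(dna))
  for (i in seq_along(dna)) {
    d <- dna[[i]]
    for (r in rna) {
      ok <- d$end1$chrom == r$end1$chrom && d$end2$chrom == r$end2$chrom &&
        abs(d$end1$pos - r$end1$pos) <= slack &&
        abs(d$end2$pos - r$end2$pos) <= slack &&
        d$end1$orientation == r$end1$orientation &&
        d$end2$orientation == r$end2$orientation
      if (ok) { keep[i] <- TRUE; break }
    }
  }
  dna[keep]
}

# positions of the spiked FOSL exon-4 break window, reused in tests
fosl_exon4 <- function(sim) sim$genes$FOSL$exons[4L, ]
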