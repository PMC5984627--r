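# Fusion-transcript reconstruction and reading-frame classification.
#
# pick_five_prime identifies the 5' partner: the break end lying inside a
# gene body with the orientation that keeps that gene's promoter on the
# retained side. NULL when neither end qualifies.

#' Identify the 5' (promoter-retaining) gene of a rearrangement
#'
#' @param r A [rearrangement].
#' @param genes Named list of [gene_model].
#' @return `NULL`, or a list with `end` (the 5' [break_end]), `gene`,
#'   `ctx` (its break context) and `other` (`"end1"`/`"end2"` naming the
#'   partner end).
#' @export
pick_five_prime <- function(r, genes) {
  for (nm in c("end1", "end2")) {
    e <- r[[nm]]
    ctx <- annotate_breakend(e, genes)
    if (is.na(ctx$gene_id)) next
    g <- genes[[ctx$gene_id]]
    promoter_side <- if (g$body$strand == "-") "retained-right" else "retained-left"
    if (e$orientation == promoter_side) {
      return(list(end = e, gene = g, ctx = ctx,
                  other = setdiff(c("end1", "end2"), nm)))
    }
  }
  NULL
}
#
# The 5' partner is the gene whose promoter is retained: its spliced exons
# are kept up to the break; an exonic break truncates the exon, an intronic
# break extends the previous exon through the retained intron (exonisation:
# the splice donor is skipped). Then comes the non-template insert, then
# plain (unspliced) partner genomic sequence to the transcript end.
# Break positions are half-open: the retained 5' segment is [start, pos).

#' Build the predicted fusion transcript for a rearrangement
#'
#' @param r A [rearrangement]; exactly one break end must lie in a gene
#'   with the orientation that retains its promoter (the 5' partner).
#' @param genes Named list of [gene_model].
#' @param genome Named `DNAStringSet`.
#' @param transcript_end Genomic position where the aberrant transcript
#'   ends on the partner side (e.g. a called or true cleavage site,
#'   exclusive bound of the transcribed interval).
#' @return A list of class `fusion_transcript` with `segments` (each a list
#'   of interval, source, sequence), `sequence`, `junction_offset`,
#'   `insert`, `cds_start`, `retained_native_len`, `gene_id`,
#'   `break_context`.
#' @export
build_fusion_transcript <- function(r, genes, genome, transcript_end) {
  pick <- pick_five_prime(r, genes)
  if (is.null(pick))
    stop("not a transcribable fusion: no break end retains a gene's promoter")
  g <- pick$gene; b <- pick$end$pos
  minus <- g$body$strand == "-"
  segs <- list()
  add_seg <- function(iv, source, seq)
    segs[[length(segs) + 1L]] <<- list(interval = iv, source = source,
                                       sequence = seq)
  seq_of <- function(s, e) {
    x <- Biostrings::subseq(genome[[g$body$chrom]], s + 1L, e)
    if (minus) as.character(Biostrings::reverseComplement(x)) else as.character(x)
  }
  fully_retained <- function(i) {
    if (minus) g$exons$start[i] >= b else g$exons$end[i] <= b
  }
  retained_native_len <- 0L
  i <- 1L
  while (i <= nrow(g$exons) && fully_retained(i)) {
    s <- g$exons$start[i]; e <- g$exons$end[i]
    add_seg(genomic_interval(g$body$chrom, s, e, g$body$strand),
            g$gene_id, seq_of(s, e))
    retained_native_len <- retained_native_len + (e - s)
    i <- i + 1L
  }
  if (pick$ctx$category == "EXONIC") {
    k <- pick$ctx$exon_index
    s <- g$exons$start[k]; e <- g$exons$end[k]
    if (minus) {
      if (b < e) add_seg(genomic_interval(g$body$chrom, b, e, "-"),
                         g$gene_id, seq_of(b, e))
      retained_native_len <- retained_native_len + (e - b)
    } else {
      if (b > s) add_seg(genomic_interval(g$body$chrom, s, b, "+"),
                         g$gene_id, seq_of(s, b))
      retained_native_len <- retained_native_len + (b - s)
    }
  } else if (pick$ctx$category == "INTRONIC" && i > 1L) {
    # exonise: extend the previous exon through the retained intron
    k <- i - 1L
    last <- segs[[length(segs)]]
    if (minus) {
      s <- b; e <- g$exons$end[k]
      segs[[length(segs)]] <- list(
        interval = genomic_interval(g$body$chrom, s, e, "-"),
        source = g$gene_id, sequence = seq_of(s, e))
    } else {
      s <- g$exons$start[k]; e <- b
      segs[[length(segs)]] <- list(
        interval = genomic_interval(g$body$chrom, s, e, "+"),
        source = g$gene_id, sequence = seq_of(s, e))
    }
  }
  junction_offset <- sum(vapply(segs, function(s) nchar(s$sequence),
                                integer(1)))

  pe <- r[[pick$other]]
  if (pe$orientation == "retained-right") {
    if (transcript_end <= pe$pos)
      stop("transcript_end must lie 3' of the partner break end")
    piv <- genomic_interval(pe$chrom, pe$pos, transcript_end, "+")
    pseq <- as.character(Biostrings::subseq(genome[[pe$chrom]],
                                            pe$pos + 1L, transcript_end))
  } else {
    if (transcript_end >= pe$pos)
      stop("transcript_end must lie 3' of the partner break end")
    piv <- genomic_interval(pe$chrom, transcript_end, pe$pos, "-")
    pseq <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[[pe$chrom]], transcript_end + 1L, pe$pos)))
  }
  pctx <- annotate_breakend(pe, genes)
  psource <- if (is.na(pctx$gene_id)) "intergenic" else pctx$gene_id
  add_seg(piv, psource, pseq)

  seqs <- vapply(segs, function(s) s$sequence, character(1))
  full <- paste0(c(seqs[seq_len(length(segs) - 1L)], r$non_template_insert,
                   seqs[length(segs)]), collapse = "")
  structure(list(segments = segs, sequence = full,
                 junction_offset = junction_offset,
                 insert = r$non_template_insert,
                 cds_start = g$cds_start,
                 retained_native_len = retained_native_len,
                 gene_id = g$gene_id, break_context = pick$ctx,
                 partner_source = psource,
                 cds = NULL, classification = NULL,
                 stop_offset_codons = NA_integer_),
            class = "fusion_transcript")
}

#' Translate a fusion transcript and classify its frame/stop outcome
#'
#' Translation starts at the 5' gene's native start codon. The first
#' in-frame stop determines `stop_offset_codons` relative to the junction
#' (floor of the nt distance over 3; negative when the stop precedes the
#' junction). Classification: `NON_CODING` if the break precedes the start
#' codon; `TRUNCATING` if the stop falls at most `stop_proximity_codons`
#' past the junction; `IN_FRAME_FUSION` if translation runs further into
#' the partner sequence before stopping; `UNTERMINATED` if no stop occurs
#' before the transcript end.
#'
#' @param ft A `fusion_transcript`.
#' @param stop_proximity_codons Codon threshold for "at or immediately
#'   after the break point". Default 10.
#' @return `ft` with `classification`, `stop_offset_codons` and `cds`
#'   filled in.
#' @export
translate_and_classify <- function(ft, stop_proximity_codons = 10L) {
  if (is.na(ft$cds_start) || ft$cds_start >= ft$junction_offset) {
    ft$classification <- "NON_CODING"
    return(ft)
  }
  coding <- substring(ft$sequence, ft$cds_start + 1L, nchar(ft$sequence))
  n3 <- (nchar(coding) %/% 3L) * 3L
  if (n3 == 0L) { ft$classification <- "UNTERMINATED"; return(ft) }
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substring(coding, 1L, n3)),
    if.fuzzy.codon = "X")))
  k <- regexpr("*", aa, fixed = TRUE)[1]
  if (k == -1L) {
    ft$classification <- "UNTERMINATED"
    return(ft)
  }
  stop_start_nt <- ft$cds_start + 3L * (k - 1L)
  ft$stop_offset_codons <- (stop_start_nt - ft$junction_offset) %/% 3L
  ft$cds <- c(start = ft$cds_start, end = stop_start_nt + 3L)
  ft$classification <- if (ft$stop_offset_codons <= stop_proximity_codons)
    "TRUNCATING" else "IN_FRAME_FUSION"
  ft
}

#' Reading-frame compatibility of a junction
#'
#' @param upstream_cds_len Nucleotides of coding sequence from the native
#'   start codon to the junction.
#' @param insert_len Length of the non-template insert.
#' @param downstream_phase Phase (0, 1, 2) of the partner coding sequence
#'   at the junction.
#' @return `TRUE` iff
#'   `(upstream_cds_len + insert_len - downstream_phase) %% 3 == 0`.
#' @export
frame_compatible <- function(upstream_cds_len, insert_len, downstream_phase) {
  stopifnot(downstream_phase %in% 0:2)
  ((upstream_cds_len + insert_len - downstream_phase) %% 3L) == 0L
}

#' Regulatory elements lost by a fusion
#'
#' An annotated element (transcript coordinates of the native 5' gene) is
#' lost unless its interval is fully contained in the retained native 5'
#' portion; an element straddling the junction is lost.
#'
#' @param ft A `fusion_transcript`.
#' @param gene The 5' partner [gene_model].
#' @return Character vector of lost element labels.
#' @export
regulatory_loss <- function(ft, gene) {
  re <- gene$regulatory_elements
  if (!nrow(re)) return(character())
  re$label[!(re$end <= ft$retained_native_len)]
}
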