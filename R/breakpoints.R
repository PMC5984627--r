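# Break-end annotation against gene models, DNA/RNA reconciliation,
# mono-allelic QC and break-point clustering.

#' Annotate a break end against the gene models
#'
#' Classifies a genomic position as EXONIC (with the 1-based exon ordinal in
#' transcript order), INTRONIC (inside a gene body but no exon) or
#' INTERGENIC. The classification is a partition: every position gets
#' exactly one category. A position exactly at an exon end (half-open
#' convention) is outside the exon, hence INTRONIC if still inside the gene
#' body.
#'
#' @param be A [break_end] (or any list with `chrom` and `pos`).
#' @param genes Named list of [gene_model].
#' @return A list with `category`, `gene_id` (NA if intergenic) and
#'   `exon_index` (NA unless exonic).
#' @export
annotate_breakend <- function(be, genes) {
  for (g in genes) {
    b <- g$body
    if (b$chrom == be$chrom && be$pos >= b$start && be$pos < b$end) {
      for (i in seq_len(nrow(g$exons))) {
        if (be$pos >= g$exons$start[i] && be$pos < g$exons$end[i]) {
          return(list(category = "EXONIC", gene_id = g$gene_id,
                      exon_index = i))
        }
      }
      return(list(category = "INTRONIC", gene_id = g$gene_id,
                  exon_index = NA_integer_))
    }
  }
  list(category = "INTERGENIC", gene_id = NA_character_,
       exon_index = NA_integer_)
}

ends_match <- function(a, b, slack) {
  a$chrom == b$chrom && abs(a$pos - b$pos) <= slack &&
    a$orientation == b$orientation
}

#' Reconcile DNA- and RNA-supported rearrangement calls
#'
#' A DNA call is retained iff some RNA call matches both break ends within
#' `slack` bp with agreeing orientations. Output positions are the DNA
#' call's; the result is always a subset of the DNA list, with evidence
#' upgraded to `"both"`.
#'
#' @param dna,rna Lists of [rearrangement] from the same sample.
#' @param slack Positional tolerance in bp (>= 0).
#' @return List of [rearrangement] with `evidence = "both"`.
#' @export
reconcile <- function(dna, rna, slack = 10L) {
  if (slack < 0) stop("reconciliation slack must be >= 0")
  kept <- Filter(function(d) {
    any(vapply(rna, function(r) {
      ends_match(d$end1, r$end1, slack) && ends_match(d$end2, r$end2, slack)
    }, logical(1)))
  }, dna)
  lapply(kept, function(d) { d$evidence <- "both"; d })
}

# junction-adjacent boundary of an aligned segment (half-open: a
# retained-left segment ends at the break position, exclusive)
segment_boundary <- function(start, end, orientation) {
  if (orientation == "retained-left") end else start
}

#' Count split-read and discordant-pair support for a junction
#'
#' Reads are supplied as a table of aligned segments: one row per split read
#' (its two segments) or per read pair (the two mates). A split read
#' supports the junction when one segment's junction-adjacent boundary lies
#' within `slack` of end1 and the other segment's boundary within `slack` of
#' end2 (in either assignment). A pair is discordant support when the two
#' mates lie on the retained sides of the two break ends, within
#' `max_frag` bp and not crossing the junction.
#'
#' @param reads data.frame with columns `qname`, `type` ("split" or
#'   "pair"), `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`
#'   (0-based half-open segment coordinates).
#' @param r A [rearrangement].
#' @param slack Tolerance in bp for split-segment boundaries.
#' @param max_frag Maximum distance from a mate to its break end.
#' @return Integer vector `c(split = , discordant = )`.
#' @export
count_supporting_reads <- function(reads, r, slack = 5L, max_frag = 1000L) {
  if (is.null(reads) || !nrow(reads))
    return(c(split = 0L, discordant = 0L))
  seg_at_end <- function(chrom, start, end, be) {
    chrom == be$chrom &&
      abs(segment_boundary(start, end, be$orientation) - be$pos) <= slack
  }
  mate_on_side <- function(chrom, start, end, be) {
    if (chrom != be$chrom) return(FALSE)
    if (be$orientation == "retained-left")
      start >= be$pos - max_frag && end <= be$pos + slack
    else
      start >= be$pos - slack && end <= be$pos + max_frag
  }
  split <- 0L; disc <- 0L
  for (i in seq_len(nrow(reads))) {
    x <- reads[i, ]
    if (x$type == "split") {
      hit <- (seg_at_end(x$chrom1, x$start1, x$end1, r$end1) &&
                seg_at_end(x$chrom2, x$start2, x$end2, r$end2)) ||
             (seg_at_end(x$chrom1, x$start1, x$end1, r$end2) &&
                seg_at_end(x$chrom2, x$start2, x$end2, r$end1))
      if (hit) split <- split + 1L
    } else {
      hit <- (mate_on_side(x$chrom1, x$start1, x$end1, r$end1) &&
                mate_on_side(x$chrom2, x$start2, x$end2, r$end2)) ||
             (mate_on_side(x$chrom1, x$start1, x$end1, r$end2) &&
                mate_on_side(x$chrom2, x$start2, x$end2, r$end1))
      if (hit) disc <- disc + 1L
    }
  }
  c(split = split, discordant = disc)
}

#' Mono-allelic QC: break points per gene per sample
#'
#' Break positions within one gene and sample are clustered by
#' single-linkage with gap `slack`; the cluster count is the number of
#' distinct break points. More than one distinct break point is flagged
#' (the expectation for these rearrangements is a single, mono-allelic
#' break per gene). This is a QC report, not a filter.
#'
#' @param calls List of [rearrangement] (reconciled), with break ends
#'   annotated by gene via `genes`.
#' @param genes Named list of [gene_model].
#' @param slack Two positions at most this far apart count as one break.
#' @return data.frame with columns `sample_id`, `gene_id`, `n_breakpoints`,
#'   `flagged`.
#' @export
check_monoallelic <- function(calls, genes, slack = 10L) {
  recs <- list()
  for (r in calls) {
    for (e in list(r$end1, r$end2)) {
      ctx <- annotate_breakend(e, genes)
      if (!is.na(ctx$gene_id)) {
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = r$sample_id, gene_id = ctx$gene_id, pos = e$pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs))
    return(data.frame(sample_id = character(), gene_id = character(),
                      n_breakpoints = integer(), flagged = logical()))
  df <- do.call(rbind, recs)
  out <- do.call(rbind, lapply(
    split(df, paste(df$sample_id, df$gene_id, sep = "\r")),
    function(d) {
      p <- sort(unique(d$pos))
      ncl <- if (length(p) == 1L) 1L else 1L + sum(diff(p) > slack)
      data.frame(sample_id = d$sample_id[1], gene_id = d$gene_id[1],
                 n_breakpoints = ncl, flagged = ncl > 1L,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Minimal window containing a set of break ends
#'
#' @param positions Integer vector of 0-based break positions within one
#'   gene (possibly across samples); must be non-empty.
#' @return Window width in bp: `max - min + 1`.
#' @export
minimal_cluster_window <- function(positions) {
  if (!length(positions)) stop("no break ends supplied")
  as.integer(max(positions) - min(positions) + 1L)
}
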