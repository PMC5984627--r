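#' Break end and rearrangement records
#'
#' A `break_end` is one oriented genomic position of a structural-variant
#' junction. Orientation `"retained-left"` means the retained (transcribed)
#' segment lies to the left of and ends at the position (half-open: the
#' position itself is the first base lost); `"retained-right"` means the
#' retained segment starts at the position. This matches the BEDPE strand
#' convention used by common SV callers (`+` = retained-left,
#' `-` = retained-right).
#'
#' @param chrom Chromosome name.
#' @param pos 0-based position of the junction base.
#' @param orientation `"retained-left"` or `"retained-right"`.
#' @return A list of class `break_end`.
#' @export
break_end <- function(chrom, pos, orientation) {
  stopifnot(orientation %in% c("retained-left", "retained-right"))
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 0L) stop("break end position must be >= 0")
  structure(list(chrom = chrom, pos = pos, orientation = orientation),
            class = "break_end")
}

#' @param end1,end2 [break_end] records; reordered so `end1 <= end2` in
#'   (chrom, pos) order.
#' @param non_template_insert Junction bases present in neither partner
#'   (may be `""`).
#' @param sample_id Sample label.
#' @param evidence `"DNA"`, `"RNA"` or `"both"`.
#' @rdname break_end
#' @return `rearrangement()`: a list of class `rearrangement` with the
#'   SV class derived from chromosomes and orientations.
#' @export
rearrangement <- function(end1, end2, non_template_insert = "",
                          sample_id = "sample", evidence = "DNA") {
  stopifnot(inherits(end1, "break_end"), inherits(end2, "break_end"),
            evidence %in% c("DNA", "RNA", "both"))
  if (nchar(non_template_insert) &&
      !grepl("^[ACGT]+$", non_template_insert))
    stop("non-template insert contains non-ACGT characters")
  if (end2$chrom < end1$chrom ||
      (end1$chrom == end2$chrom && end2$pos < end1$pos)) {
    tmp <- end1; end1 <- end2; end2 <- tmp
  }
  svclass <- if (end1$chrom != end2$chrom) "translocation"
  else {
    o <- paste(end1$orientation, end2$orientation)
    switch(o,
           "retained-left retained-right" = "deletion",
           "retained-right retained-left" = "tandem-duplication",
           "inversion")
  }
  structure(list(end1 = end1, end2 = end2,
                 non_template_insert = non_template_insert,
                 svclass = svclass, sample_id = sample_id,
                 evidence = evidence),
            class = "rearrangement")
}

#' @export
print.rearrangement <- function(x, ...) {
  cat(sprintf("<%s %s:%d(%s) -- %s:%d(%s) insert='%s' [%s, %s]>\n",
              x$svclass, x$end1$chrom, x$end1$pos, x$end1$orientation,
              x$end2$chrom, x$end2$pos, x$end2$orientation,
              x$non_template_insert, x$sample_id, x$evidence))
  invisible(x)
}

orientation_to_strand <- function(o) {
  c("retained-left" = "+", "retained-right" = "-")[[o]]
}
strand_to_orientation <- function(s) {
  if (!s %in% c("+", "-")) stop("BEDPE strand must be + or -")
  c("+" = "retained-left", "-" = "retained-right")[[s]]
}
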