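#' Genomic interval (0-based half-open)
#'
#' The single coordinate convention used throughout the package: `start` is
#' 0-based inclusive, `end` is 0-based exclusive. Conversion to and from the
#' 1-based closed convention of GFF3/VCF happens only at I/O boundaries, via
#' [zero_to_one_based()] and [one_to_zero_based()].
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop(sprintf("invalid interval %s:[%s,%s): need 0 <= start < end",
                 chrom, start, end))
  if (!strand %in% c("+", "-", "*")) stop("strand must be one of +, -, *")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d (%s)>\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

iv_width <- function(iv) iv$end - iv$start

iv_contains <- function(iv, pos) pos >= iv$start & pos < iv$end

iv_overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Coordinate-convention conversions
#'
#' Convert between the internal 0-based half-open convention and the 1-based
#' closed convention used by GFF3 and VCF. These are the only conversion
#' sites in the package.
#'
#' @param start,end Interval bounds in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
zero_to_one_based <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname zero_to_one_based
#' @export
one_to_zero_based <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @keywords internal
check_interval_in_genome <- function(iv, chrom_lengths) {
  if (!iv$chrom %in% names(chrom_lengths))
    stop(sprintf("chromosome %s not in genome", iv$chrom))
  if (iv$end > chrom_lengths[[iv$chrom]])
    stop(sprintf("interval %s:%d-%d exceeds chromosome length %d",
                 iv$chrom, iv$start, iv$end, chrom_lengths[[iv$chrom]]))
  invisible(TRUE)
}
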