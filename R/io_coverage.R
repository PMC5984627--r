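# Per-base coverage tracks. bedGraph/wiggle parsing is delegated to
# rtracklayer; the dense per-base representation over the covered span is
# this package's working form.

#' Coverage track
#'
#' Dense per-base coverage over one genomic region, with the normalisation
#' factor that has been applied (1 for raw tracks).
#'
#' @param region A [genomic_interval].
#' @param values Numeric vector, one value per base; all `>= 0`.
#' @param norm_factor Scalar multiplier already applied to `values`.
#' @return A list of class `coverage_track`.
#' @export
coverage_track <- function(region, values, norm_factor = 1) {
  stopifnot(inherits(region, "genomic_interval"))
  values <- as.numeric(values)
  if (length(values) != iv_width(region))
    stop("values length must equal region width")
  if (any(values < 0)) stop("coverage values must be >= 0")
  structure(list(region = region, values = values, norm_factor = norm_factor),
            class = "coverage_track")
}

#' Read a coverage track from bedGraph or wiggle
#'
#' The dense track spans from the first covered base to the last; uncovered
#' positions inside the span are 0. Intervals must be sorted and
#' non-overlapping within the (single) chromosome.
#'
#' @param path bedGraph (`.bedgraph`/`.bg`) or wiggle (`.wig`) file.
#' @return A [coverage_track].
#' @export
read_coverage <- function(path) {
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  if (!length(gr)) stop("coverage file is empty")
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1L)
    stop("coverage track must cover a single chromosome")
  st <- GenomicRanges::start(gr) - 1L   # to 0-based
  en <- GenomicRanges::end(gr)
  o <- order(st)
  st <- st[o]; en <- en[o]
  sc <- S4Vectors::mcols(gr)$score[o]
  if (length(st) > 1L && any(st[-1L] < en[-length(en)]))
    stop("coverage format error: overlapping intervals")
  region <- genomic_interval(as.character(GenomicRanges::seqnames(gr))[1],
                             st[1L], en[length(en)])
  vals <- numeric(iv_width(region))
  for (i in seq_along(st)) {
    vals[(st[i] - region$start + 1L):(en[i] - region$start)] <- sc[i]
  }
  coverage_track(region, vals)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into single bedGraph lines. Zero runs
#' are written explicitly so that a written track reads back bit-identically
#' (same region, same values).
#'
#' @param track A [coverage_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- rep(TRUE, length(r$values))
  lines <- sprintf("%s\t%d\t%d\t%s",
                   track$region$chrom,
                   track$region$start + starts[keep],
                   track$region$start + ends[keep],
                   format(r$values[keep], trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}
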