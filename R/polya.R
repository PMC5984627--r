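# Cryptic polyadenylation-site calling from per-base RNA coverage.
#
# The aberrant read-through transcript ends in sequence that is normally
# untranscribed; its end is taken to be 10-30 bp downstream of an AATAAA
# polyadenylation signal, at the position with the greatest coverage drop
# in the surrounding 200 bp.

#' Normalise a coverage track by the mean per-gene count
#'
#' Per-base values are divided by the mean of the per-gene counts and
#' multiplied by `norm_scale` (default 1e3), making tracks comparable
#' across samples of different library sizes.
#'
#' @param track A raw [coverage_track].
#' @param gene_counts data.frame with columns `gene`, `count`.
#' @param norm_scale Scale factor; default 1e3.
#' @return A [coverage_track] with `norm_factor = norm_scale / mean(count)`.
#' @export
normalise_coverage <- function(track, gene_counts, norm_scale = 1e3) {
  if (!nrow(gene_counts)) stop("gene count table is empty")
  m <- mean(gene_counts$count)
  if (!is.finite(m) || m <= 0)
    stop("mean gene count is zero; sample unusable for normalisation")
  f <- norm_scale / m
  coverage_track(track$region, track$values * f,
                 norm_factor = track$norm_factor * f)
}

#' Flag samples with a tumour-specific expression peak in a region
#'
#' A sample is flagged when its mean normalised coverage over the region is
#' at least `fold_threshold` times the mean of the other samples' means,
#' with a background floor (default 1 normalised unit) applied to the
#' denominator so that near-zero backgrounds do not inflate the ratio.
#'
#' @param tracks Named list of normalised [coverage_track] (>= 2 samples),
#'   all covering `region`.
#' @param region [genomic_interval] to compare over (default: intersection
#'   is assumed; the region must lie within every track).
#' @param fold_threshold Fold change required; default 5.
#' @param background_floor Minimum background mean; default 1.
#' @return Character vector of flagged sample names.
#' @export
detect_peak <- function(tracks, region, fold_threshold = 5,
                        background_floor = 1) {
  if (length(tracks) < 2L)
    stop("peak detection needs at least 2 samples")
  means <- vapply(tracks, function(tr) {
    if (region$chrom != tr$region$chrom ||
        region$start < tr$region$start || region$end > tr$region$end)
      stop("region not covered by every track")
    i0 <- region$start - tr$region$start
    mean(tr$values[(i0 + 1L):(i0 + iv_width(region))])
  }, numeric(1))
  flagged <- vapply(seq_along(means), function(i) {
    bg <- max(mean(means[-i]), background_floor)
    means[i] >= fold_threshold * bg
  }, logical(1))
  names(means)[flagged]
}

#' Scan a sequence for polyadenylation-signal motifs
#'
#' Exact occurrences of the motif on the transcribed strand, overlapping
#' matches allowed.
#'
#' @param seq Character scalar over ACGTN (transcribed-strand sequence).
#' @param motif Signal hexamer; default `"AATAAA"`.
#' @return Integer vector of 0-based motif start positions.
#' @export
scan_polya_motifs <- function(seq, motif = "AATAAA") {
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  as.integer(Biostrings::start(m)) - 1L
}

#' Call the cleavage site with the greatest coverage drop
#'
#' For every motif and every candidate end `c` at offset 10-30 bp
#' downstream of the motif's last base, the drop is the mean coverage over
#' the `drop_window/2` bases up to and including `c` minus the mean over
#' the `drop_window/2` bases after `c` (windows clipped at the track
#' edges). The call maximising the drop over all (motif, candidate) pairs
#' is returned; ties break toward the most 5' candidate. `NULL` is
#' returned when there is no motif or no positive drop.
#'
#' @param track A normalised [coverage_track].
#' @param motifs Integer vector of 0-based genomic motif start positions
#'   (e.g. from [scan_polya_motifs()] on the track region's sequence, plus
#'   the region offset).
#' @param params A [fusion_params] (uses `drop_window`,
#'   `cleavage_offset_min/max`, `polya_motif` length).
#' @return A list of class `polya_call` with `motif_site`, `cleavage_site`
#'   (0-based genomic position of the last transcribed base), `offset`
#'   (bp downstream of the motif end, in 10..30) and `drop_magnitude`,
#'   or `NULL`.
#' @export
call_cleavage_site <- function(track, motifs, params = fusion_params()) {
  if (!length(motifs)) {
    message("no polyA motif in region; no cleavage call")
    return(NULL)
  }
  w <- params$drop_window %/% 2L
  vals <- track$values
  n <- length(vals)
  r0 <- track$region$start
  mlen <- nchar(params$polya_motif)
  best <- NULL
  for (m in sort(motifs)) {
    motif_end <- m + mlen   # exclusive
    for (off in params$cleavage_offset_min:params$cleavage_offset_max) {
      cpos <- motif_end - 1L + off        # genomic, 0-based last transcribed base
      ci <- cpos - r0 + 1L                # 1-based index into vals
      if (ci < 1L || ci > n) next
      left <- vals[max(1L, ci - w + 1L):ci]
      right_lo <- ci + 1L
      right_hi <- min(n, ci + w)
      right <- if (right_lo > right_hi) numeric() else vals[right_lo:right_hi]
      drop <- mean(left) - (if (length(right)) mean(right) else 0)
      if (is.null(best) || drop > best$drop_magnitude) {
        best <- list(motif_site = m, cleavage_site = cpos, offset = off,
                     drop_magnitude = drop)
      }
    }
  }
  if (is.null(best) || best$drop_magnitude <= 0) return(NULL)
  structure(best, class = "polya_call")
}

#' Mean coverage over the mate-transcript segment and its flanks
#'
#' The mate-transcript segment runs from the break point to the cleavage
#' site; the flanks are adjacent ranges of equal length, clipped at the
#' track edges.
#'
#' @param track A [coverage_track].
#' @param break_position 0-based genomic position of the partner-side
#'   junction (first transcribed base).
#' @param cleavage_site 0-based genomic position of the last transcribed
#'   base; must be `> break_position`.
#' @return Named numeric `c(flank5 = , transcript_segment = , flank3 = )`.
#' @export
segment_means <- function(track, break_position, cleavage_site) {
  if (cleavage_site <= break_position)
    stop("cleavage site must lie 3' of the break position")
  r0 <- track$region$start
  n <- length(track$values)
  i1 <- break_position - r0 + 1L
  i2 <- cleavage_site - r0 + 1L
  if (i1 < 1L || i2 > n) stop("segment outside track")
  len <- i2 - i1 + 1L
  mid <- mean(track$values[i1:i2])
  lft <- if (i1 > 1L) track$values[max(1L, i1 - len):(i1 - 1L)] else numeric()
  rgt <- if (i2 < n) track$values[(i2 + 1L):min(n, i2 + len)] else numeric()
  c(flank5 = if (length(lft)) mean(lft) else NA_real_,
    transcript_segment = mid,
    flank3 = if (length(rgt)) mean(rgt) else NA_real_)
}
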