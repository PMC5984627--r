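#' Pipeline parameters
#'
#' Bundle of every tunable threshold used across the pipeline, with the
#' defaults the analysis is designed around. All coordinates handled by the
#' package are 0-based half-open; `bp` parameters are in base pairs.
#'
#' @param polya_motif Polyadenylation signal scanned for on the transcribed
#'   strand. Default `"AATAAA"`, the canonical hexamer.
#' @param drop_window Width in bp of the window surrounding a candidate
#'   transcript end over which the coverage drop is measured (two flanks of
#'   `drop_window / 2` each). Default 200.
#' @param cleavage_offset_min,cleavage_offset_max Permitted distance, in bp
#'   downstream of the end of the polyA motif, at which cleavage may be
#'   called. Defaults 10 and 30.
#' @param norm_scale Scale factor applied after dividing per-base coverage by
#'   the mean per-gene count. Default `1e3`.
#' @param focal_max_span Maximum span in bp for a copy-number segment to count
#'   as focal. Default `1e6`, with a strict `<` comparison.
#' @param amp_min_total_cn Minimum total copy number for a focal amplification
#'   call in a diploid genome. Default 5.
#' @param reconciliation_slack Positional tolerance in bp when matching DNA-
#'   and RNA-supported break points. Default 10.
#' @param stop_proximity_codons A stop codon at most this many codons past the
#'   junction classifies the fusion as truncating. Default 10.
#' @param peak_fold_threshold Fold change of a sample's mean normalised
#'   coverage over the background samples' mean required to flag a
#'   tumour-specific expression peak. Default 5.
#' @param min_base_qual,min_map_qual Quality filters for allele counting.
#'   Defaults 20 and 20.
#' @param rng_seed Seed recorded with a run for reproducibility. Default 1.
#'
#' @return A named list of class `fusion_params`.
#' @export
fusion_params <- function(polya_motif = "AATAAA",
                          drop_window = 200L,
                          cleavage_offset_min = 10L,
                          cleavage_offset_max = 30L,
                          norm_scale = 1e3,
                          focal_max_span = 1e6,
                          amp_min_total_cn = 5L,
                          reconciliation_slack = 10L,
                          stop_proximity_codons = 10L,
                          peak_fold_threshold = 5,
                          min_base_qual = 20L,
                          min_map_qual = 20L,
                          rng_seed = 1L) {
  if (!grepl("^[ACGT]+$", polya_motif))
    stop("polya_motif must be a non-empty ACGT string")
  if (cleavage_offset_min > cleavage_offset_max)
    stop("cleavage_offset_min must be <= cleavage_offset_max")
  for (nm in c("drop_window", "cleavage_offset_min", "cleavage_offset_max",
               "norm_scale", "focal_max_span", "amp_min_total_cn",
               "peak_fold_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop(sprintf("%s must be a single positive number", nm))
  }
  if (reconciliation_slack < 0) stop("reconciliation_slack must be >= 0")
  structure(list(
    polya_motif = polya_motif,
    drop_window = as.integer(drop_window),
    cleavage_offset_min = as.integer(cleavage_offset_min),
    cleavage_offset_max = as.integer(cleavage_offset_max),
    norm_scale = norm_scale,
    focal_max_span = focal_max_span,
    amp_min_total_cn = as.integer(amp_min_total_cn),
    reconciliation_slack = as.integer(reconciliation_slack),
    stop_proximity_codons = as.integer(stop_proximity_codons),
    peak_fold_threshold = peak_fold_threshold,
    min_base_qual = as.integer(min_base_qual),
    min_map_qual = as.integer(min_map_qual),
    rng_seed = as.integer(rng_seed)
  ), class = "fusion_params")
}
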