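# Plain TSV interchange: per-gene counts, copy-number segments, cancer-gene
# lists and per-read pileup records.

#' Read a per-gene count table
#' @param path TSV with header columns `gene`, `count`.
#' @return data.frame with columns `gene`, `count`.
#' @export
read_gene_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "count") %in% names(df)))
  df[, c("gene", "count")]
}

#' @rdname read_gene_counts
#' @param counts data.frame with columns `gene`, `count`.
#' @export
write_gene_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments
#'
#' @param path TSV with header columns `chrom`, `start`, `end` (0-based
#'   half-open), `total_cn`, `minor_cn`.
#' @return data.frame of segments.
#' @export
read_cn_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  stopifnot(all(need %in% names(df)))
  if (any(df$minor_cn > df$total_cn) || any(df$minor_cn < 0))
    stop("copy-number segment with minor_cn outside [0, total_cn]")
  df[, need]
}

#' @rdname read_cn_segments
#' @param segments data.frame of segments.
#' @export
write_cn_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cancer-gene list
#' @param path TSV with header columns `gene`, `role` (one of oncogene,
#'   TSG, both).
#' @return data.frame with columns `gene`, `role`.
#' @export
read_cancer_genes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "role") %in% names(df)))
  if (!all(df$role %in% c("oncogene", "TSG", "both")))
    stop("cancer-gene roles must be oncogene, TSG or both")
  df[, c("gene", "role")]
}

#' Read per-read pileup records for allele counting
#'
#' @param path TSV with header columns `chrom`, `pos` (0-based), `base`,
#'   `base_qual`, `map_qual`, one row per read observation.
#' @return data.frame of pileup records.
#' @export
read_pileup <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "base", "base_qual", "map_qual")
  stopifnot(all(need %in% names(df)))
  df[, need]
}

#' @rdname read_pileup
#' @param pileup data.frame of pileup records.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
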